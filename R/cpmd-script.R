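# Structured document model for CPMD input scripts. A script is an ordered
# map of &SECTION ... &END blocks; each section holds an ordered list of
# entries. An entry is either a keyword line together with its value lines
# (CPMD convention puts many values on the line *after* the keyword, e.g.
# "CHARGE" / "0"), or a raw block (a "*<pseudopotential>" species block in
# &ATOMS, a CONSTRAINTS block, ...). Lines are preserved verbatim inside
# entries, so parse -> serialize -> parse is the identity on the structure
# and unknown sections survive untouched.

new_cpmd_entry <- function(lines) {
  list(lines = as.character(lines))
}

entry_keyword <- function(entry) {
  first <- trimws(entry$lines[1])
  if (grepl("^[A-Za-z]", first)) toupper(first) else NA_character_
}

#' Parse a CPMD input script
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines, using `&SECTION` ... `&END` delimiters.
#' @return object of class `cpmd_script`.
#' @export
parse_cpmd <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  sections <- list()
  cur_name <- NULL
  cur_entries <- list()
  cur_lines <- character(0)
  flush_entry <- function() {
    if (length(cur_lines) > 0)
      cur_entries[[length(cur_entries) + 1L]] <<- new_cpmd_entry(cur_lines)
    cur_lines <<- character(0)
  }
  for (raw in lines) {
    t <- trimws(raw)
    if (!nzchar(t)) next
    if (grepl("^&", t)) {
      if (toupper(t) == "&END") {
        if (is.null(cur_name)) stop_parse("&END outside any section")
        flush_entry()
        if (toupper(cur_name) %in% toupper(names(sections)))
          stop_parse(paste0("duplicate section &", cur_name))
        sections[[toupper(cur_name)]] <- cur_entries
        cur_name <- NULL
        cur_entries <- list()
      } else {
        if (!is.null(cur_name))
          stop_parse(paste0("section &", cur_name,
                            " not terminated before &", sub("^&", "", t)))
        cur_name <- sub("^&", "", t)
      }
    } else if (is.null(cur_name)) {
      next  # stray text outside sections is ignored
    } else if (grepl("^[A-Za-z*]", t)) {
      flush_entry()
      cur_lines <- raw
    } else {
      # numeric continuation line: value line(s) of the previous entry
      cur_lines <- c(cur_lines, raw)
    }
  }
  if (!is.null(cur_name))
    stop_parse(paste0("unterminated section &", cur_name))
  structure(list(sections = sections), class = "cpmd_script")
}

#' Serialize a CPMD script to text lines
#'
#' @param s a `cpmd_script`.
#' @return character vector of lines (`&NAME` ... `&END` per section, in
#'   stored order).
#' @export
serialize_cpmd <- function(s) {
  out <- character(0)
  for (nm in names(s$sections)) {
    out <- c(out, paste0("&", nm))
    for (entry in s$sections[[nm]]) out <- c(out, entry$lines)
    out <- c(out, "&END")
  }
  out
}

#' Read/write CPMD scripts from/to files
#' @param path file path.
#' @rdname cpmd_io
#' @export
read_cpmd <- function(path) {
  if (!file.exists(path)) stop_io(paste0("CPMD input file not found: ", path))
  parse_cpmd(readLines(path, warn = FALSE))
}

#' @param s a `cpmd_script`.
#' @rdname cpmd_io
#' @export
write_cpmd <- function(s, path) {
  writeLines(serialize_cpmd(s), path)
  invisible(path)
}

#' @export
print.cpmd_script <- function(x, ...) {
  cat("<cpmd_script> sections:",
      paste0("&", names(x$sections), collapse = " "), "\n")
  invisible(x)
}

find_cpmd_entry <- function(s, section, keyword) {
  sec <- s$sections[[toupper(section)]]
  if (is.null(sec)) return(NULL)
  kw <- toupper(keyword)
  for (i in seq_along(sec)) {
    ek <- entry_keyword(sec[[i]])
    if (!is.na(ek) && (ek == kw || startsWith(ek, paste0(kw, " "))))
      return(i)
  }
  NULL
}

#' Get a keyword value from a CPMD script
#'
#' Looks up `keyword` in `section` and returns its value: tokens following
#' the keyword on the same line if any, otherwise the keyword's value
#' line(s), whitespace-collapsed. Returns `NULL` when absent. This is the
#' accessor behind idioms like reading the computed `CHARGE` out of
#' `&SYSTEM`.
#'
#' @param s a `cpmd_script`.
#' @param section,keyword section and keyword names (case-insensitive).
#' @return character scalar value or `NULL`.
#' @export
cpmd_get <- function(s, section, keyword) {
  i <- find_cpmd_entry(s, section, keyword)
  if (is.null(i)) return(NULL)
  entry <- s$sections[[toupper(section)]][[i]]
  first <- trimws(entry$lines[1])
  rest <- sub(paste0("^", keyword, "\\s*"), "", first, ignore.case = TRUE)
  if (toupper(rest) == toupper(first)) rest <- ""
  parts <- c(if (nzchar(rest)) rest, trimws(entry$lines[-1]))
  paste(parts, collapse = " ")
}

#' Set a keyword entry in a CPMD script
#'
#' Creates the section if needed; replaces an existing entry for the same
#' keyword. Values go on the line(s) after the keyword (the CPMD
#' convention), one element of `value` per line.
#'
#' @inheritParams cpmd_get
#' @param value character/numeric vector of value lines; `NULL` for a bare
#'   keyword line.
#' @param keyword_line optional full keyword line (defaults to `keyword`).
#' @return the modified `cpmd_script`.
#' @export
cpmd_set <- function(s, section, keyword, value = NULL, keyword_line = keyword) {
  section <- toupper(section)
  if (is.null(s$sections[[section]])) s$sections[[section]] <- list()
  lines <- c(keyword_line, if (!is.null(value)) paste0("    ", as.character(value)))
  i <- find_cpmd_entry(s, section, keyword)
  if (is.null(i)) i <- length(s$sections[[section]]) + 1L
  s$sections[[section]][[i]] <- new_cpmd_entry(lines)
  s
}

#' Merge generated sections into a template CPMD script
#'
#' Returns a script whose section order is: `&MIMIC` first, then the
#' template's own sections (e.g. `&CPMD`, `&DFT`) preserved verbatim, then
#' `&SYSTEM` and `&ATOMS`. Template sections with the same name as a
#' generated one are replaced.
#'
#' @param template a `cpmd_script` (may be `NULL` for no template).
#' @param generated a `cpmd_script` holding the generated sections.
#' @return the merged `cpmd_script`.
#' @export
cpmd_merge <- function(template, generated) {
  gen_names <- names(generated$sections)
  out <- list()
  lead <- intersect(c("MIMIC"), gen_names)
  for (nm in lead) out[[nm]] <- generated$sections[[nm]]
  if (!is.null(template)) {
    for (nm in names(template$sections))
      if (!(nm %in% gen_names)) out[[nm]] <- template$sections[[nm]]
  }
  for (nm in setdiff(gen_names, lead)) out[[nm]] <- generated$sections[[nm]]
  structure(list(sections = out), class = "cpmd_script")
}
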