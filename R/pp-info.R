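# Pseudopotential information table: which pseudopotential file, angular-
# momentum settings (LMAX, optionally LOC), and optionally a boundary
# (monovalent) pseudopotential file to use per element when emitting &ATOMS
# species blocks.
#
# File syntax (one record per element, "#" comments):
#   <element> <pp_filename> LMAX=<l> [LOC=<l>] [<boundary_pp_filename>]

#' Construct a pseudopotential information table
#'
#' @param element character vector of element symbols.
#' @param pp_filename pseudopotential file name per element.
#' @param lmax LMAX value per element (e.g. `"S"`, `"P"`, `"D"`).
#' @param loc optional LOC value per element (`NA` to omit).
#' @param boundary_filename optional monovalent boundary pseudopotential file
#'   per element (`NA` when the element never sits on a cut bond).
#' @return object of class `pp_info`.
#' @export
pp_info <- function(element, pp_filename, lmax, loc = NA_character_,
                    boundary_filename = NA_character_) {
  el <- normalize_element(element)
  if (anyNA(el))
    stop_usage(paste0("unknown element symbol(s) in pp table: ",
                      paste(element[is.na(el)], collapse = ", ")))
  tab <- data.frame(element = el, pp_filename = pp_filename, lmax = lmax,
                    loc = loc, boundary_filename = boundary_filename,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$element))
    stop_usage("duplicate element entries in pp table")
  structure(list(table = tab), class = "pp_info")
}

#' Read a pseudopotential information file
#'
#' @param path path to the text file described above.
#' @return a [pp_info()] table.
#' @export
read_pp_info <- function(path) {
  if (!file.exists(path)) stop_io(paste0("pp info file not found: ", path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_parse(paste0(path, ": empty pp info file"))
  rows <- lapply(lines, function(line) {
    tk <- strsplit(line, "\\s+")[[1]]
    if (length(tk) < 3 || !grepl("^LMAX=", toupper(tk[3])))
      stop_parse(paste0(path, ": expected '<element> <file> LMAX=<l> ",
                        "[LOC=<l>] [<boundary file>]', got: ", line))
    loc <- NA_character_
    bnd <- NA_character_
    rest <- tk[-(1:3)]
    if (length(rest) > 0 && grepl("^LOC=", toupper(rest[1]))) {
      loc <- sub("^LOC=", "", rest[1], ignore.case = TRUE)
      rest <- rest[-1]
    }
    if (length(rest) > 0) bnd <- rest[1]
    data.frame(element = tk[1], pp_filename = tk[2],
               lmax = sub("^LMAX=", "", tk[3], ignore.case = TRUE),
               loc = loc, boundary_filename = bnd, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pp_info(tab$element, tab$pp_filename, tab$lmax, tab$loc,
          tab$boundary_filename)
}

#' Write a pseudopotential information file
#' @param pp a [pp_info()] table.
#' @param path output path.
#' @export
write_pp_info <- function(pp, path) {
  t <- pp$table
  lines <- sprintf("%-3s %s LMAX=%s%s%s", t$element, t$pp_filename, t$lmax,
                   ifelse(is.na(t$loc), "", paste0(" LOC=", t$loc)),
                   ifelse(is.na(t$boundary_filename), "",
                          paste0(" ", t$boundary_filename)))
  writeLines(c("# element  pp_file  LMAX=<l> [LOC=<l>] [boundary_pp_file]",
               lines), path)
  invisible(path)
}

pp_lookup <- function(pp, element, boundary = FALSE) {
  i <- match(element, pp$table$element)
  if (is.na(i))
    stop_usage(paste0("no pseudopotential entry for element ", element))
  row <- pp$table[i, ]
  if (boundary) {
    if (is.na(row$boundary_filename))
      stop_usage(paste0("no boundary pseudopotential for element ", element))
    row$pp_filename <- row$boundary_filename
  }
  row
}

#' @export
print.pp_info <- function(x, ...) {
  cat(sprintf("<pp_info> %d element(s): %s\n", nrow(x$table),
              paste(x$table$element, collapse = ", ")))
  invisible(x)
}
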