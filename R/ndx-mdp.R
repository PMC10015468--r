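# GROMACS index (.ndx) and run-parameter (.mdp) file handlers.

#' Construct a GROMACS index file object
#'
#' @param groups named list of positive 1-based atom index vectors.
#' @return object of class `ndx_file`.
#' @export
ndx_file <- function(groups = list()) {
  for (nm in names(groups)) {
    idx <- groups[[nm]]
    if (length(idx) > 0 && (any(idx < 1) || anyNA(idx)))
      stop_usage(paste0("index group '", nm, "' has non-positive indices"))
    groups[[nm]] <- as.integer(idx)
  }
  structure(list(groups = groups), class = "ndx_file")
}

#' @export
print.ndx_file <- function(x, ...) {
  for (nm in names(x$groups))
    cat(sprintf("[ %s ]: %d atoms\n", nm, length(x$groups[[nm]])))
  invisible(x)
}

#' Write a GROMACS index file
#'
#' Serializes each group as `[ name ]` followed by its indices, wrapped at
#' 15 indices per line.
#'
#' @param n an [ndx_file()] with at least one nonempty group.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ndx <- function(n, path) {
  if (length(n$groups) == 0 || any(lengths(n$groups) == 0))
    stop_usage("no atoms selected: refusing to write an empty index group")
  out <- character(0)
  for (nm in names(n$groups)) {
    idx <- n$groups[[nm]]
    rows <- split(idx, (seq_along(idx) - 1L) %/% 15L)
    out <- c(out, sprintf("[ %s ]", nm),
             vapply(rows, function(r) paste(r, collapse = " "), ""))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a GROMACS index file
#' @param path path to a `.ndx` file.
#' @return an [ndx_file()].
#' @export
read_ndx <- function(path) {
  if (!file.exists(path)) stop_io(paste0("index file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  hdr <- grepl("^\\[.*\\]$", lines)
  if (!any(hdr)) stop_parse(paste0(path, ": no index groups"))
  grp <- cumsum(hdr)
  names <- trimws(gsub("^\\[|\\]$", "", lines[hdr]))
  groups <- lapply(split(lines[!hdr], grp[!hdr]), function(body)
    as.integer(unlist(strsplit(body, "\\s+"))))
  out <- stats::setNames(vector("list", length(names)), names)
  for (g in names(groups)) out[[as.integer(g)]] <- groups[[g]]
  out[vapply(out, is.null, TRUE)] <- list(integer(0))
  ndx_file(out)
}

# -- mdp ---------------------------------------------------------------------

#' Parse a GROMACS mdp file
#'
#' Keeps comments and line order so that a patched file differs from its
#' template only in the patched keys. Key matching is GROMACS-style
#' case-insensitive with `-` and `_` interchangeable.
#'
#' @param path path to a `.mdp` file.
#' @return object of class `mdp_file`: a data.frame of entries with columns
#'   `kind` (`pair`, `comment`, `blank`), `key`, `value`, `comment`.
#' @export
read_mdp <- function(path) {
  if (!file.exists(path)) stop_io(paste0("mdp file not found: ", path))
  parse_mdp(readLines(path, warn = FALSE))
}

#' @param lines character vector of mdp lines.
#' @rdname read_mdp
#' @export
parse_mdp <- function(lines) {
  rows <- lapply(lines, function(line) {
    t <- trimws(line)
    if (!nzchar(t))
      return(data.frame(kind = "blank", key = NA, value = NA, comment = NA,
                        stringsAsFactors = FALSE))
    if (startsWith(t, ";"))
      return(data.frame(kind = "comment", key = NA, value = NA, comment = t,
                        stringsAsFactors = FALSE))
    cmt <- NA_character_
    if (grepl(";", t)) {
      cmt <- sub("^[^;]*", "", t)
      t <- trimws(sub(";.*$", "", t))
    }
    if (!grepl("=", t))
      stop_parse(paste0("mdp line without '=': ", line))
    key <- trimws(sub("=.*$", "", t))
    value <- trimws(sub("^[^=]*=", "", t))
    data.frame(kind = "pair", key = key, value = value, comment = cmt,
               stringsAsFactors = FALSE)
  })
  structure(list(entries = do.call(rbind, rows)), class = "mdp_file")
}

mdp_norm_key <- function(key) tolower(gsub("[-_]", "", key))

#' Get an mdp parameter value
#' @param m an `mdp_file`.
#' @param key parameter name.
#' @return character value or `NULL`.
#' @export
mdp_get <- function(m, key) {
  e <- m$entries
  i <- which(e$kind == "pair" & mdp_norm_key(e$key) == mdp_norm_key(key))
  if (length(i) == 0) return(NULL)
  e$value[tail(i, 1)]
}

#' Set mdp parameters, preserving everything else
#'
#' @param m an `mdp_file`.
#' @param required named character vector of `key = value` settings; existing
#'   keys are updated in place, new keys appended.
#' @return the patched `mdp_file`.
#' @export
patch_mdp <- function(m, required) {
  e <- m$entries
  for (key in names(required)) {
    i <- which(e$kind == "pair" & mdp_norm_key(e$key) == mdp_norm_key(key))
    if (length(i) > 0) {
      e$value[i] <- as.character(required[[key]])
    } else {
      e <- rbind(e, data.frame(kind = "pair", key = key,
                               value = as.character(required[[key]]),
                               comment = NA, stringsAsFactors = FALSE))
    }
  }
  structure(list(entries = e), class = "mdp_file")
}

#' Serialize / write an mdp file
#' @param m an `mdp_file`.
#' @return character vector of lines.
#' @export
serialize_mdp <- function(m) {
  e <- m$entries
  vapply(seq_len(nrow(e)), function(i) {
    switch(e$kind[i],
      blank = "",
      comment = e$comment[i],
      pair = paste0(sprintf("%-24s = %s", e$key[i], e$value[i]),
                    if (!is.na(e$comment[i])) paste0("  ", e$comment[i]) else ""))
  }, "")
}

#' @param path output path.
#' @rdname serialize_mdp
#' @export
write_mdp <- function(m, path) {
  writeLines(serialize_mdp(m), path)
  invisible(path)
}

#' @export
print.mdp_file <- function(x, ...) {
  n <- sum(x$entries$kind == "pair")
  cat(sprintf("<mdp_file> %d parameter(s)\n", n))
  invisible(x)
}
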