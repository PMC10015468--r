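# Coordinate I/O: one unit-normalized tabular representation for the four
# supported formats (GROMACS gro, PDB, XYZ, CPMD GEOMETRY). Internally all
# coordinates are nanometers; each writer converts back to its native unit.

COORD_FORMATS <- c("gro", "pdb", "xyz", "cpmd_geometry")

#' Construct a coordinate set
#'
#' A `coordinate_set` is the common in-memory currency for all coordinate
#' formats: an ordered per-atom table plus an optional periodic box, with all
#' lengths in nanometers.
#'
#' @param atoms data.frame with columns `serial` (1-based integer, strictly
#'   increasing), `atom_name`, `residue_name`, `residue_id`, `chain_or_mol`,
#'   and coordinates `x`, `y`, `z` in nm.
#' @param box numeric length-3 vector of box lengths in nm, or `NULL`.
#' @param source_format one of `"gro"`, `"pdb"`, `"xyz"`, `"cpmd_geometry"`,
#'   or `NA` for sets built in code.
#' @return object of class `coordinate_set`.
#' @export
coordinate_set <- function(atoms, box = NULL, source_format = NA_character_) {
  required <- c("serial", "atom_name", "residue_name", "residue_id",
                "chain_or_mol", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop_usage(paste0("atoms table lacks column(s): ",
                      paste(missing_cols, collapse = ", ")))
  atoms <- as.data.frame(atoms)[required]
  rownames(atoms) <- NULL
  xyz <- as.matrix(atoms[c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop_parse("non-finite coordinates in atom table")
  if (anyDuplicated(atoms$serial) || is.unsorted(atoms$serial, strictly = TRUE))
    stop_usage("atom serials must be unique and strictly increasing")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || !all(is.finite(box)) || any(box <= 0))
      stop_usage("box must have three strictly positive components")
  }
  structure(list(atoms = atoms, box = box, source_format = source_format),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("<coordinate_set> %d atoms", nrow(x$atoms)))
  if (!is.null(x$box))
    cat(sprintf(", box %.3f x %.3f x %.3f nm", x$box[1], x$box[2], x$box[3]))
  if (!is.na(x$source_format)) cat(sprintf(" [%s]", x$source_format))
  cat("\n")
  invisible(x)
}

infer_coord_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  base <- toupper(basename(path))
  if (ext == "gro") return("gro")
  if (ext == "pdb") return("pdb")
  if (ext == "xyz") return("xyz")
  if (ext == "" || grepl("^GEOMETRY", base)) return("cpmd_geometry")
  stop_usage(paste0("cannot infer coordinate format from extension '.", ext,
                    "'; pass format= explicitly"))
}

#' Read a coordinate file
#'
#' Reads GROMACS gro, PDB, XYZ, or CPMD GEOMETRY files into a common
#' [coordinate_set()] with coordinates in nanometers (gro is native nm;
#' pdb/xyz Angstrom are scaled by 0.1; GEOMETRY Bohr by 0.0529177210903).
#'
#' @param path path to the coordinate file.
#' @param format one of `"gro"`, `"pdb"`, `"xyz"`, `"cpmd_geometry"`;
#'   inferred from the file name when `NULL` (`GEOMETRY`/extension-less files
#'   are taken as CPMD GEOMETRY).
#' @return a [coordinate_set()].
#' @export
read_coordinates <- function(path, format = NULL) {
  if (!file.exists(path))
    stop_io(paste0("coordinate file not found: ", path))
  format <- if (is.null(format)) infer_coord_format(path)
            else match.arg(format, COORD_FORMATS)
  lines <- readLines(path, warn = FALSE)
  switch(format,
    gro = read_gro_lines(lines, path),
    pdb = read_pdb_lines(lines, path),
    xyz = read_xyz_lines(lines, path),
    cpmd_geometry = read_geometry_lines(lines, path))
}

num_field <- function(s, path, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  bad <- is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s))
  if (any(bad))
    stop_parse(sprintf("%s: line %d: non-numeric %s field '%s'",
                       path, lineno[which(bad)[1]], what, s[which(bad)[1]]))
  v
}

# gro is parsed strictly fixed-width (resid 1-5, resname 6-10, name 11-15,
# serial 16-20, coordinates in three 8.3f fields); names adjacent to digits
# make whitespace splitting unsafe.
read_gro_lines <- function(lines, path) {
  if (length(lines) < 3) stop_parse(paste0(path, ": truncated gro file"))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1)
    stop_parse(paste0(path, ": line 2: invalid atom count"))
  if (length(lines) < 2 + n + 1)
    stop_parse(sprintf("%s: expected %d atom lines plus a box line", path, n))
  body <- lines[3:(2 + n)]
  lineno <- seq_along(body) + 2L
  short <- nchar(body) < 44
  if (any(short))
    stop_parse(sprintf("%s: line %d: gro atom line shorter than 44 columns",
                       path, lineno[which(short)[1]]))
  atoms <- data.frame(
    serial = seq_len(n),
    atom_name = trimws(substr(body, 11, 15)),
    residue_name = trimws(substr(body, 6, 10)),
    residue_id = as.integer(num_field(substr(body, 1, 5), path, lineno, "residue id")),
    chain_or_mol = "",
    x = num_field(substr(body, 21, 28), path, lineno, "x"),
    y = num_field(substr(body, 29, 36), path, lineno, "y"),
    z = num_field(substr(body, 37, 44), path, lineno, "z"),
    stringsAsFactors = FALSE)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[2 + n + 1]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3 || anyNA(boxv[1:3]))
    stop_parse(sprintf("%s: line %d: invalid box line", path, 2 + n + 1))
  box <- boxv[1:3]
  if (any(box <= 0)) box <- NULL
  coordinate_set(atoms, box = box, source_format = "gro")
}

read_pdb_lines <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  sel <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(sel)) stop_parse(paste0(path, ": no ATOM/HETATM records"))
  body <- lines[sel]
  lineno <- which(sel)
  box <- NULL
  cryst <- lines[trimws(rec) == "CRYST1"]
  if (length(cryst) >= 1) {
    abc <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))))
    if (!anyNA(abc) && all(abc > 0)) box <- abc * ANG_NM
  }
  atoms <- data.frame(
    serial = seq_along(body),
    atom_name = trimws(substr(body, 13, 16)),
    residue_name = trimws(substr(body, 18, 21)),
    residue_id = as.integer(num_field(substr(body, 23, 26), path, lineno,
                                      "residue sequence")),
    chain_or_mol = trimws(substr(body, 22, 22)),
    x = num_field(substr(body, 31, 38), path, lineno, "x") * ANG_NM,
    y = num_field(substr(body, 39, 46), path, lineno, "y") * ANG_NM,
    z = num_field(substr(body, 47, 54), path, lineno, "z") * ANG_NM,
    stringsAsFactors = FALSE)
  coordinate_set(atoms, box = box, source_format = "pdb")
}

read_xyz_lines <- function(lines, path) {
  if (length(lines) < 3) stop_parse(paste0(path, ": truncated xyz file"))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop_parse(paste0(path, ": line 1: invalid atom count"))
  if (length(lines) < 2 + n)
    stop_parse(sprintf("%s: expected %d atom lines", path, n))
  body <- lines[3:(2 + n)]
  lineno <- seq_along(body) + 2L
  toks <- strsplit(trimws(body), "\\s+")
  bad <- vapply(toks, length, 0L) < 4
  if (any(bad))
    stop_parse(sprintf("%s: line %d: xyz atom line needs symbol + 3 coordinates",
                       path, lineno[which(bad)[1]]))
  coords <- t(vapply(toks, function(t)
    suppressWarnings(as.numeric(t[2:4])), numeric(3)))
  if (anyNA(coords)) {
    i <- which(apply(is.na(coords), 1, any))[1]
    stop_parse(sprintf("%s: line %d: non-numeric coordinate", path, lineno[i]))
  }
  atoms <- data.frame(
    serial = seq_len(n),
    atom_name = vapply(toks, `[`, "", 1L),
    residue_name = "MOL",
    residue_id = 1L,
    chain_or_mol = "",
    x = coords[, 1] * ANG_NM,
    y = coords[, 2] * ANG_NM,
    z = coords[, 3] * ANG_NM,
    stringsAsFactors = FALSE)
  coordinate_set(atoms, box = NULL, source_format = "xyz")
}

# CPMD GEOMETRY dialect: one line per atom; the first three whitespace-
# separated floats are positions in Bohr. A leading non-numeric token is kept
# as the atom name; any trailing columns (velocities) are ignored.
read_geometry_lines <- function(lines, path) {
  keep <- nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0) stop_parse(paste0(path, ": empty GEOMETRY file"))
  lineno <- which(keep)
  parse_one <- function(toks, ln) {
    first_num <- suppressWarnings(as.numeric(toks[1]))
    if (is.na(first_num)) {
      name <- toks[1]
      vals <- suppressWarnings(as.numeric(toks[2:4]))
    } else {
      name <- "X"
      vals <- suppressWarnings(as.numeric(toks[1:3]))
    }
    if (length(vals) < 3 || anyNA(vals))
      stop_parse(sprintf("%s: line %d: expected three Bohr coordinates",
                         path, ln))
    list(name = name, xyz = vals)
  }
  toks <- strsplit(trimws(body), "\\s+")
  parsed <- Map(parse_one, toks, lineno)
  xyz <- t(vapply(parsed, `[[`, numeric(3), "xyz")) * BOHR_NM
  atoms <- data.frame(
    serial = seq_along(parsed),
    atom_name = vapply(parsed, `[[`, "", "name"),
    residue_name = "MOL",
    residue_id = 1L,
    chain_or_mol = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  coordinate_set(atoms, box = NULL, source_format = "cpmd_geometry")
}

#' Write a coordinate set to file
#'
#' Serializes a [coordinate_set()] to one of the supported dialects: gro
#' (fixed-width, nm, `%8.3f`), PDB (ATOM records, Angstrom to 3 decimals,
#' occupancy/B-factor written as 1.00/0.00), XYZ (count + comment header,
#' Angstrom), or CPMD GEOMETRY (Bohr, zero velocity columns).
#'
#' gro output requires a box; when absent one is synthesized from the
#' coordinate extent plus a 0.1 nm margin on each side, with a warning.
#' Serial/residue fields wider than their fixed-width columns wrap modulo the
#' field width (gro/pdb, > 99999 atoms) with a warning.
#'
#' @param cs a nonempty [coordinate_set()].
#' @param path output file path.
#' @param format target format; defaults to the set's `source_format`.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(cs, path, format = NULL) {
  if (!inherits(cs, "coordinate_set"))
    stop_usage("cs must be a coordinate_set")
  if (nrow(cs$atoms) == 0)
    stop_usage("refusing to write an empty coordinate set")
  if (is.null(format)) {
    if (is.na(cs$source_format))
      stop_usage("no format given and coordinate set has no source format")
    format <- cs$source_format
  }
  format <- match.arg(format, COORD_FORMATS)
  lines <- switch(format,
    gro = format_gro(cs),
    pdb = format_pdb(cs),
    xyz = format_xyz(cs),
    cpmd_geometry = format_geometry(cs))
  writeLines(lines, path)
  invisible(path)
}

wrap_serial <- function(serial, width = 5L) {
  lim <- 10L^width
  if (any(serial >= lim)) {
    warning(sprintf("atom serials exceed %d; wrapping modulo %d", lim - 1, lim),
            call. = FALSE)
    serial <- serial %% lim
  }
  serial
}

format_gro <- function(cs) {
  a <- cs$atoms
  box <- cs$box
  if (is.null(box)) {
    warning("gro output needs a box; synthesizing from coordinate extent + 0.1 nm margin",
            call. = FALSE)
    ext <- apply(a[c("x", "y", "z")], 2, function(v) diff(range(v)))
    box <- ext + 0.2
  }
  serial <- wrap_serial(a$serial)
  resid <- a$residue_id %% 100000L
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  resid, substr(a$residue_name, 1, 5),
                  substr(a$atom_name, 1, 5), serial, a$x, a$y, a$z)
  c("Written by mimicprep", sprintf("%5d", nrow(a)), body,
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

# PDB convention: 1-3 character atom names start in column 14.
pdb_pad_name <- function(name) {
  name <- substr(name, 1, 4)
  ifelse(nchar(name) < 4, sprintf("%-4s", paste0(" ", name)), name)
}

format_pdb <- function(cs) {
  a <- cs$atoms
  serial <- wrap_serial(a$serial)
  resid <- a$residue_id %% 10000L
  body <- sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  serial, pdb_pad_name(a$atom_name),
                  substr(a$residue_name, 1, 4),
                  substr(paste0(a$chain_or_mol, " "), 1, 1), resid,
                  a$x / ANG_NM, a$y / ANG_NM, a$z / ANG_NM, 1, 0)
  header <- character(0)
  if (!is.null(cs$box))
    header <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                      cs$box[1] / ANG_NM, cs$box[2] / ANG_NM,
                      cs$box[3] / ANG_NM, 90, 90, 90)
  c(header, body, "END")
}

format_xyz <- function(cs) {
  a <- cs$atoms
  c(sprintf("%d", nrow(a)), "Written by mimicprep",
    sprintf("%-4s %12.6f %12.6f %12.6f", a$atom_name,
            a$x / ANG_NM, a$y / ANG_NM, a$z / ANG_NM))
}

format_geometry <- function(cs) {
  a <- cs$atoms
  sprintf("%18.10f %18.10f %18.10f %18.10f %18.10f %18.10f",
          a$x / BOHR_NM, a$y / BOHR_NM, a$z / BOHR_NM, 0, 0, 0)
}
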