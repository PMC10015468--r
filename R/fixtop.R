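# FixTop: consolidate atomic-species information into a topology so that a
# downstream QM engine (and the index map, which needs elements for MM atoms
# too) can rely on it. The whole include tree is copied into an output
# directory; the consolidated [ atomtypes ] registry — every type with its
# atomic number and mass filled — replaces the body of the nonbonded
# force-field include. When no include looks like a nonbonded file, a new
# "atomtypes_fixed.itp" is written and #include'd at the top of the copied
# topology (and recognized as the consolidation target on a re-run, which
# makes fix_top idempotent).

collect_top_files <- function(path, include_dirs, depth = 0L,
                              chain = character()) {
  path <- normalizePath(path)
  chain <- c(chain, path)
  if (length(chain) > 50)
    stop_io(paste0("#include nesting too deep: ", paste(chain, collapse = " -> ")))
  acc <- data.frame(path = path, depth = depth, stringsAsFactors = FALSE)
  for (line in readLines(path, warn = FALSE)) {
    t <- trimws(strip_top_comment(line))
    if (grepl("^#include\\s+", t)) {
      target <- sub('^#include\\s+["<]([^">]+)[">].*', "\\1", t)
      inc <- resolve_include(target, path, include_dirs, chain)
      sub_acc <- collect_top_files(inc, include_dirs, depth + 1L, chain)
      acc <- rbind(acc, sub_acc)
    }
  }
  acc[!duplicated(acc$path), , drop = FALSE]
}

# Output-relative name: files next to the root topology keep their basename;
# files elsewhere (a force-field directory) go under <dirname-basename>/.
fixtop_out_rel <- function(path, top_dir) {
  d <- normalizePath(dirname(path))
  if (d == top_dir) basename(path)
  else file.path(basename(d), basename(path))
}

# Path to write into a rewritten #include, from the including file's new
# location to the target's new location.
fixtop_include_ref <- function(from_rel, to_rel) {
  if (dirname(from_rel) == dirname(to_rel)) return(basename(to_rel))
  if (dirname(from_rel) == ".") return(to_rel)
  file.path("..", to_rel)
}

# [ atomtypes ] section spans on raw (unpreprocessed) lines: a span runs from
# its header to the line before the next section header or preprocessor
# directive.
atomtypes_spans <- function(lines) {
  stripped <- trimws(vapply(lines, strip_top_comment, "", USE.NAMES = FALSE))
  hdr <- grepl("^\\[\\s*atomtypes\\s*\\]$", stripped)
  any_hdr <- grepl("^\\[", stripped) | grepl("^#", stripped)
  lapply(which(hdr), function(s) {
    nxt <- which(any_hdr & seq_along(lines) > s)
    e <- if (length(nxt) == 0) length(lines) else nxt[1] - 1L
    c(s, e)
  })
}

consolidated_atomtypes_block <- function(registry) {
  charge <- ifelse(is.na(registry$charge), 0, registry$charge)
  ptype <- ifelse(is.na(registry$ptype) | !nzchar(registry$ptype), "A",
                  registry$ptype)
  body <- sprintf("%-10s %4d %10.5f %10.5f  %s  %s",
                  registry$type_name, registry$at_num, registry$mass,
                  charge, ptype, registry$tail)
  c("[ atomtypes ]",
    "; name     at.num       mass     charge  ptype  (nonbonded params)",
    sub("\\s+$", "", body), "")
}

replace_spans <- function(lines, spans, replacements) {
  if (length(spans) == 0) return(lines)
  keep <- rep(TRUE, length(lines))
  for (sp in spans) keep[sp[1]:sp[2]] <- FALSE
  out <- list(); last <- 0L
  for (i in seq_along(spans)) {
    sp <- spans[[i]]
    if (sp[1] > last + 1L) out <- c(out, list(lines[(last + 1L):(sp[1] - 1L)]))
    out <- c(out, list(replacements[[i]]))
    last <- sp[2]
  }
  if (last < length(lines)) out <- c(out, list(lines[(last + 1L):length(lines)]))
  unlist(out)
}

#' Repair element information in a GROMACS topology
#'
#' Parses a topology, infers the element of every atom type (see
#' [guess_elements()]), and writes a copy of the topology and its whole
#' `#include` tree into `ff_dir_out` with a consolidated `[ atomtypes ]`
#' section in which every type carries its atomic number and mass. The
#' consolidated section replaces the body of the deepest included file whose
#' name contains `"nonbonded"`; when there is none, it is written to a new
#' `atomtypes_fixed.itp` included at the top of the copied topology. The
#' repaired topology resolves all species with guessing disabled, and
#' running `fix_top` on its own output reproduces it byte for byte.
#'
#' @param top_path path to the `.top` file.
#' @param ff_dir_out output directory (created if needed); must not be the
#'   directory holding `top_path`.
#' @param clear_sections when `TRUE`, remove all other `[ atomtypes ]`
#'   sections from the copied files (the `-cls` behaviour); otherwise they
#'   are preserved verbatim.
#' @param nsa_table optional atom-type to element map consulted before
#'   guessing.
#' @param include_dirs,defines passed to [read_topology()].
#' @return invisibly, a list with `top` (path of the repaired `.top`),
#'   `target` (file holding the consolidated section) and `files` (all
#'   written paths).
#' @export
fix_top <- function(top_path, ff_dir_out, clear_sections = FALSE,
                    nsa_table = NULL, include_dirs = character(),
                    defines = character()) {
  if (!file.exists(top_path))
    stop_io(paste0("topology file not found: ", top_path))
  top_dir <- normalizePath(dirname(top_path))
  dir.create(ff_dir_out, showWarnings = FALSE, recursive = TRUE)
  if (normalizePath(ff_dir_out) == top_dir)
    stop_usage("ff_dir_out must differ from the directory of the input topology")

  top <- read_topology(top_path, include_dirs, defines)
  top <- guess_elements(top, nsa_table = nsa_table)
  reg <- top$atom_types
  # types never used by an atom still need species info in the registry
  for (i in which(is.na(reg$element))) {
    g <- guess_element_one(reg$mass[i], reg$type_name[i], reg$type_name[i],
                           nsa_table)
    reg$element[i] <- g$element
  }
  if (anyNA(reg$element))
    stop_chem(paste0("cannot consolidate [ atomtypes ]: unresolved type(s) ",
                     paste(reg$type_name[is.na(reg$element)], collapse = ", ")))
  reg$at_num <- element_z(reg$element)
  reg$mass[is.na(reg$mass)] <- periodic_table()$mass[match(reg$element[is.na(reg$mass)],
                                                           periodic_table()$symb)]
  block <- consolidated_atomtypes_block(reg)

  tree <- collect_top_files(top_path, include_dirs)
  tree$rel <- vapply(tree$path, fixtop_out_rel, "", top_dir = top_dir)
  nb <- grepl("nonbonded", basename(tree$path), ignore.case = TRUE) |
        basename(tree$path) == "atomtypes_fixed.itp"
  target_idx <- if (any(nb)) which(nb)[which.max(tree$depth[nb])] else NA_integer_

  written <- character(0)
  for (k in seq_len(nrow(tree))) {
    src <- tree$path[k]
    rel <- tree$rel[k]
    lines <- readLines(src, warn = FALSE)
    # rewrite includes to the copied layout
    for (i in seq_along(lines)) {
      t <- trimws(strip_top_comment(lines[i]))
      if (grepl("^#include\\s+", t)) {
        tgt <- sub('^#include\\s+["<]([^">]+)[">].*', "\\1", t)
        inc <- normalizePath(resolve_include(tgt, src, include_dirs, src))
        to_rel <- tree$rel[match(inc, tree$path)]
        lines[i] <- sprintf('#include "%s"', fixtop_include_ref(rel, to_rel))
      }
    }
    spans <- atomtypes_spans(lines)
    if (!is.na(target_idx) && k == target_idx) {
      if (length(spans) == 0) {
        lines <- c(block, lines)
      } else {
        reps <- c(list(block), rep(list(character(0)), length(spans) - 1L))
        lines <- replace_spans(lines, spans, reps)
      }
    } else if (clear_sections && length(spans) > 0) {
      lines <- replace_spans(lines, spans, rep(list(character(0)), length(spans)))
    }
    if (is.na(target_idx) && k == 1L)
      lines <- c('#include "atomtypes_fixed.itp"', lines)
    out_path <- file.path(ff_dir_out, rel)
    dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, out_path)
    written <- c(written, out_path)
  }
  if (is.na(target_idx)) {
    target_path <- file.path(ff_dir_out, "atomtypes_fixed.itp")
    writeLines(block, target_path)
    written <- c(written, target_path)
  } else {
    target_path <- file.path(ff_dir_out, tree$rel[target_idx])
  }
  out_top <- file.path(ff_dir_out, tree$rel[1])
  log_info("fix_top wrote ", length(written), " file(s); consolidated ",
           "[ atomtypes ] in ", target_path)
  invisible(list(top = out_top, target = target_path, files = written))
}
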