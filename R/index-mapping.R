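# GROMACS -> CPMD index translation. CPMD numbers atoms by species blocks,
# not in topology order, so locating an atom (an MM atom especially) in the
# CPMD input requires reproducing that reordering. The rule implemented
# here, centralized in build_index_map() so it can be swapped if the engine
# convention differs:
#   * QM atoms take CPMD ids 1..|QM| in &ATOMS emission order: non-boundary
#     species blocks by ascending atomic number, boundary blocks last (also
#     by ascending atomic number), ascending GROMACS index within a block;
#   * MM atoms take ids |QM|+1..N grouped by species in ascending atomic
#     number, ascending GROMACS index within a species.

#' Build the GROMACS-to-CPMD index map
#'
#' Constructs the bijection between GROMACS global atom ids and CPMD atom
#' ids for a given QM region (see the ordering rule above). Every atom —
#' MM atoms included — must have a resolved element; repair the topology
#' with [fix_top()] or [guess_elements()] first.
#'
#' @param top a `topology` with elements resolved for all atoms.
#' @param region integer vector of global atom ids forming the QM region
#'   (may be empty, making every atom MM).
#' @param boundary_ids QM atoms to place in the trailing boundary blocks;
#'   computed with [detect_boundary_atoms()] when `NULL`.
#' @return object of class `index_map`: data.frame with columns `gmx_id`,
#'   `cpmd_id`, `partition` (`"qm"`/`"mm"`), `species`, `is_boundary`,
#'   `name`, `resid`.
#' @export
build_index_map <- function(top, region, boundary_ids = NULL) {
  ga <- top$global_atoms
  region <- sort(unique(as.integer(region)))
  if (length(region) > 0 && (min(region) < 1 || max(region) > nrow(ga)))
    stop_usage("region contains atom ids outside the topology")
  if (anyNA(ga$element)) {
    bad <- unique(ga$type[is.na(ga$element)])
    stop_chem(paste0("the index map needs an element for every atom, but ",
                     "type(s) ", paste(bad, collapse = ", "),
                     " are unresolved; run fix_top or guess_elements first"))
  }
  if (is.null(boundary_ids)) boundary_ids <- detect_boundary_atoms(top, region)
  z <- element_z(ga$element)
  is_qm <- ga$id %in% region
  is_bnd <- ga$id %in% boundary_ids
  qm <- ga$id[is_qm]
  qm <- qm[order(is_bnd[qm], z[qm], qm)]
  mm <- ga$id[!is_qm]
  mm <- mm[order(z[mm], mm)]
  ordered <- c(qm, mm)
  map <- data.frame(
    gmx_id = ordered,
    cpmd_id = seq_along(ordered),
    partition = c(rep("qm", length(qm)), rep("mm", length(mm))),
    species = ga$element[ordered],
    is_boundary = is_bnd[ordered],
    name = ga$name[ordered],
    resid = ga$resid[ordered],
    stringsAsFactors = FALSE)
  map <- map[order(map$gmx_id), ]
  rownames(map) <- NULL
  structure(map, class = c("index_map", "data.frame"))
}

#' @export
print.index_map <- function(x, ...) {
  nqm <- sum(x$partition == "qm")
  cat(sprintf("<index_map> %d atoms (%d QM, %d MM)\n", nrow(x), nqm,
              nrow(x) - nqm))
  invisible(x)
}

cpmd_ids_for <- function(map, ids) {
  j <- match(ids, map$gmx_id)
  if (anyNA(j))
    stop_usage(paste0("atom id(s) not in the index map: ",
                      paste(ids[is.na(j)], collapse = ", ")))
  map$cpmd_id[j]
}

format_id_ranges <- function(cpmd_ids) {
  ids <- sort(unique(cpmd_ids))
  breaks <- c(0, which(diff(ids) != 1), length(ids))
  runs <- vapply(seq_len(length(breaks) - 1L), function(k) {
    a <- ids[breaks[k] + 1L]; b <- ids[breaks[k + 1L]]
    if (a == b) sprintf("%d", a) else sprintf("%d-%d", a, b)
  }, "")
  paste(runs, collapse = ",")
}

#' Format CPMD indices for a set of atoms
#'
#' @param map an [build_index_map()] result.
#' @param ids GROMACS global atom ids to report.
#' @param style `"table"` (columns: GROMACS id, CPMD id, name, resid,
#'   species — for debugging), `"list"` (space-separated CPMD ids — for
#'   pasting into an input), or `"range"` (maximal runs `a-b` of consecutive
#'   CPMD ids, comma-joined — e.g. for thermostat groups).
#' @return character vector of output lines (a single line for list/range).
#' @export
format_indices <- function(map, ids, style = c("table", "list", "range")) {
  style <- match.arg(style)
  if (length(ids) == 0) {
    message("empty selection: nothing to print")
    return(character(0))
  }
  cpmd <- cpmd_ids_for(map, ids)
  if (style == "list")
    return(paste(sort(cpmd), collapse = " "))
  if (style == "range")
    return(format_id_ranges(cpmd))
  j <- match(ids, map$gmx_id)
  ord <- order(map$cpmd_id[j])
  c(sprintf("%10s %10s %6s %6s %8s",
            "gromacs_id", "cpmd_id", "name", "resid", "species"),
    sprintf("%10d %10d %6s %6d %8s",
            map$gmx_id[j][ord], map$cpmd_id[j][ord], map$name[j][ord],
            map$resid[j][ord], map$species[j][ord]))
}
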