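# The preparation engine: holds the QM selection against a topology +
# coordinate set, computes the QM cell and total charge, detects
# open-valence boundary atoms, and emits the MiMiC-compliant CPMD input
# together with the GROMACS index file.

#' Create a preparation object
#'
#' Binds a topology to a coordinate set (matched by atom order; both must
#' describe the same number of atoms) and holds the growing QM region.
#'
#' @param top a [read_topology()] result.
#' @param coords a [read_coordinates()] result.
#' @return object of class `preparation`.
#' @export
preparation <- function(top, coords) {
  if (!inherits(top, "topology")) stop_usage("top must be a topology")
  if (!inherits(coords, "coordinate_set"))
    stop_usage("coords must be a coordinate_set")
  if (n_atoms(top) != nrow(coords$atoms))
    stop_usage(sprintf(
      "topology (%d atoms) and coordinates (%d atoms) do not match",
      n_atoms(top), nrow(coords$atoms)))
  structure(list(top = top, coords = coords, region = integer(0)),
            class = "preparation")
}

#' @export
print.preparation <- function(x, ...) {
  cat(sprintf("<preparation> %d atoms, %d selected as QM\n",
              n_atoms(x$top), length(x$region)))
  invisible(x)
}

#' Add or delete atoms in the QM region
#'
#' `qm_add()` unions the atoms matched by a selection into the QM region;
#' `qm_delete()` removes them. Both are idempotent; deleting atoms that are
#' not in the region warns with the count of ignored atoms.
#'
#' @param prep a [preparation()] object.
#' @param query a selection string or [parse_query()] result.
#' @return the updated `preparation`.
#' @export
qm_add <- function(prep, query) {
  hits <- evaluate_selection(query, prep$top)
  prep$region <- sort(union(prep$region, hits))
  prep
}

#' @rdname qm_add
#' @export
qm_delete <- function(prep, query) {
  hits <- evaluate_selection(query, prep$top)
  absent <- setdiff(hits, prep$region)
  if (length(absent) > 0)
    warning(sprintf("%d matched atom(s) were not in the QM region", length(absent)),
            call. = FALSE)
  prep$region <- setdiff(prep$region, hits)
  prep
}

#' Compute the QM cell from the region extent
#'
#' Per axis, the cell length is the coordinate extent of the QM atoms plus
#' `2 * padding_nm` — a minimal distance between the QM atoms and the cell
#' boundary, required by the Poisson solver for isolated systems (Martyna-
#' Tuckerman). The default padding of 0.35 nm is a lower bound in practice;
#' larger systems typically need more.
#'
#' @param coords a [coordinate_set()].
#' @param region integer vector of atom ids (row serials), nonempty.
#' @param padding_nm padding in nm, `>= 0`.
#' @return list with `lengths_bohr`, `lengths_nm` (each a named 3-vector),
#'   `origin_nm` (the region's minimum corner) and `padding_nm`.
#' @export
compute_qm_box <- function(coords, region, padding_nm = 0.35) {
  if (length(region) == 0) stop_usage("QM region is empty")
  if (padding_nm < 0) stop_usage("padding must be >= 0")
  a <- coords$atoms[match(region, coords$atoms$serial), , drop = FALSE]
  if (anyNA(a$serial)) stop_usage("region ids not present in coordinate set")
  mins <- c(min(a$x), min(a$y), min(a$z))
  maxs <- c(max(a$x), max(a$y), max(a$z))
  lengths_nm <- (maxs - mins) + 2 * padding_nm
  if (any(lengths_nm <= 0))
    stop_usage("QM cell has zero volume: degenerate extent with zero padding")
  names(lengths_nm) <- c("a", "b", "c")
  list(lengths_bohr = lengths_nm * NM_BOHR, lengths_nm = lengths_nm,
       origin_nm = stats::setNames(mins, c("x", "y", "z")),
       padding_nm = padding_nm)
}

#' Total charge of the QM region
#'
#' Sums the partial charges of the region's atoms and rounds to the nearest
#' integer — the CHARGE reported in `&SYSTEM`. A non-integral sum (beyond
#' 0.01 e) warns: it is the signature of a selection severing a charge
#' group, typical of bond-cutting QM regions.
#'
#' @param top a `topology`.
#' @param region integer vector of global atom ids.
#' @return list with `raw_sum` (e) and `declared` (integer).
#' @export
compute_qm_charge <- function(top, region) {
  q <- top$global_atoms$charge[match(region, top$global_atoms$id)]
  raw <- sum(q)
  declared <- as.integer(round(raw))
  if (abs(raw - declared) > 0.01)
    warning(sprintf(
      "QM charge sum %.4f e is not integral (declared %d); the selection may sever a charge group",
      raw, declared), call. = FALSE)
  list(raw_sum = raw, declared = declared)
}

#' Detect open-valence boundary atoms
#'
#' Returns the QM atoms having at least one bonded neighbour outside the
#' region — atoms on a severed covalent bond, which must be described by a
#' special monovalent boundary pseudopotential.
#'
#' @param top a `topology` with its bond list.
#' @param region integer vector of global atom ids.
#' @return ascending integer vector of boundary atom ids (possibly empty).
#' @export
detect_boundary_atoms <- function(top, region) {
  b <- top$global_bonds
  if (nrow(b) == 0 || length(region) == 0) return(integer(0))
  in_region <- logical(n_atoms(top))
  in_region[region] <- TRUE
  cut <- xor(in_region[b[, 1]], in_region[b[, 2]])
  sort(unique(c(b[cut, 1][in_region[b[cut, 1]]],
                b[cut, 2][in_region[b[cut, 2]]])))
}

# Emission order of QM atoms in &ATOMS (and hence their CPMD ids):
# non-boundary species blocks by ascending atomic number, boundary blocks
# last, ascending GROMACS index within a block. Single source of truth
# shared with build_index_map().
order_qm_atoms <- function(ids, z, is_boundary) {
  ids[order(is_boundary, z, ids)]
}

# Resolve elements for the QM atoms only (the FixTop tool handles MM atoms).
resolve_region_elements <- function(top, region, nsa_table = NULL, guess = TRUE) {
  ga <- top$global_atoms
  rows <- match(region, ga$id)
  todo <- rows[is.na(ga$element[rows])]
  for (i in todo) {
    if (!guess) {
      el <- if (!is.null(nsa_table) && ga$type[i] %in% names(nsa_table))
        normalize_element(nsa_table[[ga$type[i]]]) else NA_character_
    } else {
      el <- guess_element_one(ga$mass[i], ga$name[i], ga$type[i], nsa_table)$element
    }
    ga$element[i] <- el
  }
  bad <- unique(ga$type[rows][is.na(ga$element[rows])])
  if (length(bad) > 0)
    stop_chem(paste0("cannot resolve the element of QM atom type(s): ",
                     paste(bad, collapse = ", "),
                     if (!guess) " (guessing is disabled; supply an nsa table)"))
  top$global_atoms <- ga
  top
}

#' Generate the MiMiC input files for the current QM region
#'
#' The centrepiece of the workflow: merges the generated `&MIMIC`, `&SYSTEM`
#' and `&ATOMS` sections into the template CPMD script (whose other
#' sections, e.g. `&CPMD`/`&DFT`, are preserved verbatim), builds the
#' GROMACS index group of QM atoms, and optionally patches an mdp template
#' (`integrator = mimic`, `QMMM-grps = <group>`).
#'
#' `&MIMIC` holds PATHS (the directory of the GROMACS tpr file), BOX (the MM
#' box in Bohr) and OVERLAPS (one line per QM atom pairing its GROMACS index
#' with its CPMD index). `&ATOMS` holds one species block per element —
#' header `*<pp_filename>`, an LMAX/LOC line, the atom count, then absolute
#' Bohr coordinates shifted so the region's minimum corner sits at
#' `(padding, padding, padding)`, centring the region in the minimal cell.
#' Boundary atoms form separate trailing blocks using the boundary
#' pseudopotential. `&SYSTEM` carries the declared integer CHARGE and the
#' QM cell.
#'
#' @param prep a [preparation()] with a nonempty region.
#' @param pp a [pp_info()] table covering every region element (and the
#'   boundary entries when `boundary = TRUE`).
#' @param template optional template `cpmd_script` (or path).
#' @param tpr_path path of the GROMACS tpr file the MiMiC run will use;
#'   only its directory enters PATHS.
#' @param padding_nm QM cell padding in nm (default 0.35).
#' @param boundary enable the boundary-atom treatment; when `FALSE` and cut
#'   bonds exist, generation stops with an explanatory error.
#' @param mdp optional template `mdp_file` (or path) to patch.
#' @param nsa_table,guess element resolution for QM atoms lacking species
#'   information (see [guess_elements()]); MM atoms are left to [fix_top()].
#' @param ndx_group index group name (default `"QMatoms"`).
#' @return list with `cpmd` (`cpmd_script`), `ndx` (`ndx_file`), `mdp`
#'   (patched `mdp_file` or `NULL`), `map` (the QM part of the index map),
#'   `charge`, `box`, and `boundary_ids`.
#' @export
generate_mimic_input <- function(prep, pp, template = NULL,
                                 tpr_path = "mimic.tpr", padding_nm = 0.35,
                                 boundary = FALSE, mdp = NULL,
                                 nsa_table = NULL, guess = TRUE,
                                 ndx_group = "QMatoms") {
  region <- prep$region
  if (length(region) == 0)
    stop_usage("no atoms selected: the QM region is empty")
  if (is.character(template)) template <- read_cpmd(template)
  if (is.character(mdp)) mdp <- read_mdp(mdp)
  if (is.character(pp)) pp <- read_pp_info(pp)

  top <- resolve_region_elements(prep$top, region, nsa_table, guess)
  ga <- top$global_atoms

  bnd <- detect_boundary_atoms(top, region)
  if (length(bnd) > 0 && !boundary)
    stop_chem(paste0(
      length(bnd), " QM atom(s) have bonds crossing the QM-MM boundary, ",
      "leaving open valences; re-run with the boundary option enabled ",
      "to assign monovalent boundary pseudopotentials"))

  z <- element_z(ga$element)
  is_bnd <- ga$id %in% bnd
  qm_order <- order_qm_atoms(region, z[region], is_bnd[region])
  cpmd_id <- stats::setNames(seq_along(qm_order), qm_order)

  charge <- compute_qm_charge(top, region)
  box <- compute_qm_box(prep$coords, region, padding_nm)

  # species blocks partition the region: (element, is_boundary) groups
  key_bnd <- is_bnd[qm_order]
  key_el <- ga$element[qm_order]
  blocks <- split(qm_order, list(el = key_el, bnd = key_bnd), drop = TRUE)
  blk_el <- vapply(strsplit(names(blocks), "\\."), `[`, "", 1L)
  blk_bnd <- vapply(strsplit(names(blocks), "\\."), `[`, "", 2L) == "TRUE"
  ord <- order(blk_bnd, element_z(blk_el))
  blocks <- blocks[ord]; blk_el <- blk_el[ord]; blk_bnd <- blk_bnd[ord]

  missing_el <- setdiff(unique(blk_el), pp$table$element)
  if (length(missing_el) > 0)
    stop_usage(paste0("pp table lacks entries for element(s): ",
                      paste(missing_el, collapse = ", ")))

  co <- prep$coords$atoms
  shift <- box$origin_nm - padding_nm
  atoms_lines <- character(0)
  for (k in seq_along(blocks)) {
    ids <- blocks[[k]]
    row <- pp_lookup(pp, blk_el[k], boundary = blk_bnd[k])
    lmax_line <- paste0("   LMAX=", row$lmax,
                        if (!is.na(row$loc)) paste0(" LOC=", row$loc))
    rows <- match(ids, co$serial)
    xyz <- cbind(co$x[rows] - shift[1], co$y[rows] - shift[2],
                 co$z[rows] - shift[3]) * NM_BOHR
    atoms_lines <- c(atoms_lines,
      paste0("*", row$pp_filename), lmax_line,
      sprintf("%5d", length(ids)),
      sprintf(" %17.10f %17.10f %17.10f", xyz[, 1], xyz[, 2], xyz[, 3]))
  }

  if (is.null(prep$coords$box))
    stop_usage("the MM coordinate set has no box; &MIMIC needs the MM cell")
  mm_box_bohr <- prep$coords$box * NM_BOHR

  gen <- structure(list(sections = list()), class = "cpmd_script")
  gen <- cpmd_set(gen, "MIMIC", "PATHS",
                  value = c("1", normalizePath(dirname(tpr_path), mustWork = FALSE)))
  gen <- cpmd_set(gen, "MIMIC", "BOX",
                  value = paste(sprintf("%.10f", mm_box_bohr), collapse = " "))
  overlap_lines <- sprintf("%8d", length(qm_order))
  overlap_lines <- c(overlap_lines,
                     sprintf("2 %7d 1 %7d", qm_order, seq_along(qm_order)))
  gen$sections[["MIMIC"]][[length(gen$sections[["MIMIC"]]) + 1L]] <-
    new_cpmd_entry(c("OVERLAPS", paste0("    ", overlap_lines)))
  gen <- cpmd_set(gen, "SYSTEM", "CELL", keyword_line = "CELL ABSOLUTE",
                  value = paste(sprintf("%.10f", c(box$lengths_bohr, 0, 0, 0)),
                                collapse = " "))
  gen <- cpmd_set(gen, "SYSTEM", "CHARGE", value = sprintf("%d", charge$declared))
  gen$sections[["ATOMS"]] <- lapply(
    split(atoms_lines, cumsum(startsWith(atoms_lines, "*"))),
    new_cpmd_entry)
  names(gen$sections[["ATOMS"]]) <- NULL

  out_cpmd <- cpmd_merge(template, gen)
  ndx <- ndx_file(stats::setNames(list(sort(qm_order)), ndx_group))
  out_mdp <- if (!is.null(mdp))
    patch_mdp(mdp, c(integrator = "mimic", "QMMM-grps" = ndx_group))

  map <- data.frame(gmx_id = qm_order, cpmd_id = seq_along(qm_order),
                    stringsAsFactors = FALSE)
  log_info(sprintf("QM region: %d atoms, charge %+d (raw %.4f e), cell %.3f x %.3f x %.3f Bohr",
                   length(region), charge$declared, charge$raw_sum,
                   box$lengths_bohr[1], box$lengths_bohr[2], box$lengths_bohr[3]))
  list(cpmd = out_cpmd, ndx = ndx, mdp = out_mdp, map = map,
       charge = charge, box = box, boundary_ids = bnd)
}
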