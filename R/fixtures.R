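# Deterministic generators of small synthetic test systems, written as
# standard .top/.itp/.gro files. Two scenarios are emulated: a nonstandard
# small molecule (a 10-atom ketone with no species information in
# [ atomtypes ]) solvated in 3-site waters constrained via [ settles ], and
# a linear peptide-like chain whose side-chain selections sever covalent
# bonds. Ground-truth annotations (true elements, expected selections,
# expected boundary atoms, charge sums) are returned alongside the files.
# Coordinates are quantized to 3 decimals (nm) so gro round-trips exactly;
# the same (arguments, seed) always produce byte-identical files.

quant3 <- function(x) round(x, 3)

ketone_template <- function() {
  # rough acetone-like geometry, nm, centred on the carbonyl carbon
  data.frame(
    name = c("C1", "O1", "C2", "H21", "H22", "H23", "C3", "H31", "H32", "H33"),
    type = c("c_ket", "o_ket", "c_me", "h_me", "h_me", "h_me",
             "c_me", "h_me", "h_me", "h_me"),
    charge = c(0.55, -0.55, -0.3, 0.1, 0.1, 0.1, -0.3, 0.1, 0.1, 0.1),
    x = c(0, 0, -0.128, -0.215, -0.12, -0.15, 0.128, 0.215, 0.12, 0.15),
    y = c(0, 0.122, -0.077, -0.013, -0.16, -0.11, -0.077, -0.013, -0.16, -0.11),
    z = c(0, 0, 0, 0.03, 0.07, -0.1, 0, 0.03, 0.07, -0.1),
    stringsAsFactors = FALSE)
}

KETONE_MASSES <- c(c_ket = 12.011, o_ket = 15.9994, c_me = 12.011, h_me = 1.008)
KETONE_ELEMENTS <- c(c_ket = "C", o_ket = "O", c_me = "C", h_me = "H",
                     ow = "O", hw = "H")

random_atom_names <- function(n) {
  letters_pool <- c(LETTERS, letters)
  vapply(seq_len(n), function(i)
    paste0(paste(sample(letters_pool, 2, replace = TRUE), collapse = ""),
           sample(0:9, 1)), "")
}

#' Generate a solvated small-molecule test system
#'
#' Builds a 10-atom nonstandard ketone (zero net charge, realistic masses,
#' no element information in `[ atomtypes ]`) surrounded by `n_waters`
#' 3-site waters with settles-style constraints, on a jittered grid inside
#' a cubic box. Writes `topol.top`, `acetone.itp`, `water.itp` and
#' `coords.gro` under `dir`.
#'
#' @param n_waters number of water molecules (>= 0).
#' @param seed integer seed; same arguments and seed give byte-identical
#'   files.
#' @param dir output directory (created; defaults to a fresh temp dir).
#' @param scramble_names replace the ketone atom names with random strings,
#'   so only the mass rule can recover elements.
#' @return a `fixture_system` list: `dir`, `top`, `gro`, `n_atoms`, and
#'   `annotations` (`true_elements` by type, `qm_query`,
#'   `expected_region`, `expected_boundary`, `mol_charges`).
#' @export
make_solvated_small_molecule <- function(n_waters = 5, seed = 1,
                                         dir = tempfile("solvated"),
                                         scramble_names = FALSE) {
  if (n_waters < 0) stop_usage("n_waters must be >= 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_seed(seed, {
    ket <- ketone_template()
    if (scramble_names) ket$name <- random_atom_names(nrow(ket))

    atomtypes <- c(
      "[ atomtypes ]",
      "; name        mass    charge  ptype     sigma   epsilon",
      sprintf("%-6s %9.5f %9.5f  A  %8.6f %8.6f",
              c("c_ket", "o_ket", "c_me", "h_me", "ow", "hw"),
              c(12.011, 15.9994, 12.011, 1.008, 15.9994, 1.008),
              c(0, 0, 0, 0, 0, 0),
              c(0.339967, 0.295992, 0.339967, 0.264953, 0.315061, 0),
              c(0.359824, 0.87864, 0.45773, 0.065689, 0.636386, 0)))

    acetone_itp <- c(
      "[ moleculetype ]",
      "ACT   3",
      "[ atoms ]",
      ";  nr  type  resnr  resname  atom  cgnr  charge",
      sprintf("%5d %-6s %5d  ACT  %-5s %5d %9.5f",
              seq_len(10), ket$type, 1L, ket$name, seq_len(10), ket$charge),
      "[ bonds ]",
      sprintf("%4d %4d  1",
              c(1, 1, 1, 3, 3, 3, 7, 7, 7), c(2, 3, 7, 4, 5, 6, 8, 9, 10)))

    water_itp <- c(
      "[ moleculetype ]",
      "SOL   2",
      "[ atoms ]",
      "1  ow  1  SOL  OW   1  -0.834  15.9994",
      "2  hw  1  SOL  HW1  1   0.417   1.008",
      "3  hw  1  SOL  HW2  1   0.417   1.008",
      "#ifdef FLEXIBLE",
      "[ bonds ]",
      "1 2 1",
      "1 3 1",
      "#else",
      "[ settles ]",
      "1  1  0.09572  0.15139",
      "#endif",
      "[ exclusions ]",
      "1 2 3",
      "2 1 3",
      "3 1 2")

    topol <- c("; solvated nonstandard ketone test system",
               atomtypes,
               '#include "acetone.itp"',
               '#include "water.itp"',
               "[ system ]",
               "Ketone in water",
               "[ molecules ]",
               "ACT   1",
               sprintf("SOL   %d", n_waters))

    writeLines(topol, file.path(dir, "topol.top"))
    writeLines(acetone_itp, file.path(dir, "acetone.itp"))
    writeLines(water_itp, file.path(dir, "water.itp"))

    # coordinates: ketone at the box centre, waters on a jittered grid
    m <- max(2L, ceiling((n_waters + 2)^(1 / 3)))
    spacing <- 0.45
    box_len <- quant3(spacing * (m + 1))
    centre <- box_len / 2
    grid <- expand.grid(ix = seq_len(m), iy = seq_len(m), iz = seq_len(m))
    gpos <- as.matrix(grid) * spacing
    d_centre <- sqrt(rowSums((gpos - centre)^2))
    gpos <- gpos[order(-d_centre), , drop = FALSE]  # outermost cells first
    if (n_waters > nrow(gpos))
      stop_usage("n_waters too large for the internal grid")

    rows <- list()
    rows[[1]] <- data.frame(
      serial = seq_len(10), atom_name = ket$name, residue_name = "ACT",
      residue_id = 1L, chain_or_mol = "",
      x = quant3(ket$x + centre), y = quant3(ket$y + centre),
      z = quant3(ket$z + centre), stringsAsFactors = FALSE)
    if (n_waters > 0) {
      for (w in seq_len(n_waters)) {
        p <- gpos[w, ] + stats::runif(3, -0.05, 0.05)
        rows[[w + 1]] <- data.frame(
          serial = 10L + 3L * (w - 1L) + 1:3,
          atom_name = c("OW", "HW1", "HW2"), residue_name = "SOL",
          residue_id = 1L + w, chain_or_mol = "",
          x = quant3(p[1] + c(0, 0.096, -0.024)),
          y = quant3(p[2] + c(0, 0, 0.093)),
          z = quant3(p[3] + c(0, 0, 0)), stringsAsFactors = FALSE)
      }
    }
    atoms <- do.call(rbind, rows)
    cs <- coordinate_set(atoms, box = rep(box_len, 3), source_format = "gro")
    write_coordinates(cs, file.path(dir, "coords.gro"), "gro")

    true_elements <- KETONE_ELEMENTS
    structure(list(
      dir = dir,
      top = file.path(dir, "topol.top"),
      gro = file.path(dir, "coords.gro"),
      n_atoms = 10L + 3L * n_waters,
      annotations = list(
        true_elements = true_elements,
        qm_query = "resname is ACT",
        expected_region = 1:10,
        expected_boundary = integer(0),
        mol_charges = c(ACT = 0, SOL = 0))),
      class = "fixture_system")
  })
}

PEPTIDE_ATOMS <- data.frame(
  name = c("N", "CA", "C", "O", "CB1", "CB2"),
  type = c("n_bb", "c_a", "c_c", "o_c", "c_s", "c_s"),
  charge = c(-0.4, 0.1, 0.5, -0.5, 0.2, 0.1),
  dx = c(0.00, 0.12, 0.26, 0.30, 0.10, 0.12),
  dy = c(0.00, 0.10, 0.06, -0.06, 0.24, 0.38),
  dz = c(0.00, 0.00, 0.04, 0.10, 0.00, 0.06),
  stringsAsFactors = FALSE)

#' Generate a peptide-like chain test system
#'
#' Builds a linear chain of `n_residues` toy residues, each with a backbone
#' (N, CA, C, O) and a 2-atom side chain (CB1 bonded to CA, CB2 to CB1),
#' connected by peptide bonds C(i)-N(i+1). Elements are declared through an
#' `at.num` column in `[ atomtypes ]`. Writes `pep.top` and `pep.gro`.
#'
#' @param n_residues chain length (>= 2).
#' @param seed integer seed (coordinate jitter).
#' @param dir output directory.
#' @param charged_residues residue indices given a net charge of +1 (added
#'   to their CB2 atom), emulating basic side chains.
#' @return a `fixture_system` list; `annotations` carries per-residue id
#'   helpers: `residue_ids(i)`, `sidechain_ids(i)`, `sidechain_query(i)`,
#'   `expected_sidechain_boundary(i)` (the CB1 global id), and
#'   `n_bonds`.
#' @export
make_peptide_chain <- function(n_residues = 3, seed = 1,
                               dir = tempfile("peptide"),
                               charged_residues = integer(0)) {
  if (n_residues < 2) stop_usage("n_residues must be >= 2")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_preserved_seed(seed, {
    per <- PEPTIDE_ATOMS
    n_per <- nrow(per)
    n <- n_residues * n_per

    atoms_lines <- character(0)
    for (i in seq_len(n_residues)) {
      charge <- per$charge
      if (i %in% charged_residues) charge[6] <- charge[6] + 1.0
      atoms_lines <- c(atoms_lines,
        sprintf("%5d %-5s %5d  RES  %-4s %5d %9.5f",
                (i - 1L) * n_per + seq_len(n_per), per$type, i, per$name,
                (i - 1L) * n_per + seq_len(n_per), charge))
    }
    intra <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      b <- (i - 1L) * n_per
      rbind(c(b + 1, b + 2), c(b + 2, b + 3), c(b + 3, b + 4),
            c(b + 2, b + 5), c(b + 5, b + 6))
    }))
    peptide <- if (n_residues > 1)
      cbind((seq_len(n_residues - 1L) - 1L) * n_per + 3L,
            seq_len(n_residues - 1L) * n_per + 1L)
    bonds <- rbind(intra, peptide)

    top <- c(
      "; peptide-like chain test system",
      "[ atomtypes ]",
      "; name  at.num      mass    charge  ptype     sigma   epsilon",
      sprintf("%-5s %4d %9.5f %9.5f  A  %8.6f %8.6f",
              c("n_bb", "c_a", "c_c", "o_c", "c_s"),
              c(7, 6, 6, 8, 6),
              c(14.0067, 12.011, 12.011, 15.9994, 12.011),
              c(0, 0, 0, 0, 0),
              c(0.325, 0.34, 0.34, 0.296, 0.34),
              c(0.711, 0.457, 0.457, 0.879, 0.457)),
      "[ moleculetype ]",
      "PEP   3",
      "[ atoms ]",
      atoms_lines,
      "[ bonds ]",
      sprintf("%4d %4d  1", bonds[, 1], bonds[, 2]),
      "[ system ]",
      "Toy peptide chain",
      "[ molecules ]",
      "PEP   1")
    writeLines(top, file.path(dir, "pep.top"))

    step <- 0.42
    coords <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      base <- c((i - 1) * step + 0.3, 0.6, 0.6)
      jit <- stats::runif(3, -0.02, 0.02)
      data.frame(
        serial = (i - 1L) * n_per + seq_len(n_per),
        atom_name = per$name, residue_name = "RES", residue_id = i,
        chain_or_mol = "",
        x = quant3(base[1] + jit[1] + per$dx),
        y = quant3(base[2] + jit[2] + per$dy),
        z = quant3(base[3] + jit[3] + per$dz), stringsAsFactors = FALSE)
    }))
    box <- c(quant3(n_residues * step + 1), 1.8, 1.8)
    cs <- coordinate_set(coords, box = box, source_format = "gro")
    write_coordinates(cs, file.path(dir, "pep.gro"), "gro")

    residue_ids <- function(i) (i - 1L) * n_per + seq_len(n_per)
    sidechain_ids <- function(i) (i - 1L) * n_per + 5:6
    structure(list(
      dir = dir,
      top = file.path(dir, "pep.top"),
      gro = file.path(dir, "pep.gro"),
      n_atoms = n,
      annotations = list(
        n_bonds = nrow(bonds),
        residue_ids = residue_ids,
        sidechain_ids = sidechain_ids,
        sidechain_query = function(i)
          sprintf("resid is %d and (name is CB1 or name is CB2)", i),
        expected_sidechain_boundary = function(i) (i - 1L) * n_per + 5L,
        charged_residues = charged_residues)),
      class = "fixture_system")
  })
}

#' @export
print.fixture_system <- function(x, ...) {
  cat(sprintf("<fixture_system> %d atoms in %s\n", x$n_atoms, x$dir))
  invisible(x)
}
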