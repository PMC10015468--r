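px <- fixture_preparation(n_waters = 5, seed = 1)
prep0 <- px$prep

test_that("add and delete behave as idempotent set operations", {
  p1 <- qm_add(prep0, "resname is ACT")
  expect_equal(p1$region, 1:10)
  expect_equal(qm_add(p1, "resname is ACT")$region, p1$region)
  expect_equal(qm_delete(p1, "resname is ACT")$region, integer(0))
  expect_warning(qm_delete(p1, "resname is SOL"), "not in the QM region")
})

test_that("the QM cell is the region extent plus twice the padding", {
  # two atoms 1 nm apart with the default 0.35 nm pad: 1.7 nm = 32.125 Bohr
  cs <- coordinate_set(data.frame(
    serial = 1:2, atom_name = c("C1", "C2"), residue_name = "MOL",
    residue_id = 1L, chain_or_mol = "",
    x = c(0, 1), y = c(0, 0.2), z = c(0, 0.1)))
  box <- compute_qm_box(cs, 1:2, padding_nm = 0.35)
  expect_equal(round(box$lengths_bohr[["a"]], 3), 32.125)
  expect_equal(box$lengths_nm[["a"]], 1.7)

  expect_error(compute_qm_box(cs, 1L, padding_nm = 0),
               class = "mimicprep_usage_error")
  expect_error(compute_qm_box(cs, integer(0)),
               class = "mimicprep_usage_error")

  # property: length - extent = 2 * padding on random clouds
  set.seed(31)
  for (i in 1:20) {
    n <- 100
    cloud <- coordinate_set(data.frame(
      serial = seq_len(n), atom_name = "X", residue_name = "MOL",
      residue_id = 1L, chain_or_mol = "",
      x = runif(n, 0, 4), y = runif(n, 0, 4), z = runif(n, 0, 4)))
    pad <- runif(1, 0, 1)
    b <- compute_qm_box(cloud, seq_len(n), pad)
    ext <- vapply(cloud$atoms[c("x", "y", "z")], function(v) diff(range(v)), 0)
    expect_lt(max(abs(b$lengths_nm - ext - 2 * pad)), 1e-9)
    expect_lt(max(abs(b$lengths_bohr - b$lengths_nm / 0.0529177210903)), 1e-9)
  }
})

test_that("the declared charge is the rounded region sum, warning on cuts", {
  expect_equal(compute_qm_charge(prep0$top, 1:10)$declared, 0L)
  expect_equal(compute_qm_charge(prep0$top, 1:10)$raw_sum, 0, tolerance = 1e-9)

  # two charged residues: +1 each
  pep <- make_peptide_chain(4, seed = 2, charged_residues = c(2, 3))
  ptop <- read_topology(pep$top)
  region <- c(pep$annotations$residue_ids(2), pep$annotations$residue_ids(3))
  ch <- compute_qm_charge(ptop, region)
  expect_equal(ch$declared, 2L)
  expect_equal(ch$raw_sum, 2, tolerance = 1e-9)

  # severing a charge group leaves a non-integral sum
  expect_warning(ch2 <- compute_qm_charge(prep0$top, 1L), "not integral")
  expect_equal(ch2$raw_sum, 0.55, tolerance = 1e-9)
  expect_equal(ch2$declared, 1L)
})

test_that("boundary atoms are exactly the QM atoms bonded outside the region", {
  pep <- make_peptide_chain(3, seed = 1)
  ptop <- read_topology(pep$top)
  an <- pep$annotations

  # side chains of residues 1 and 3: the two CB1 atoms sit on cut CA-CB1 bonds
  region <- c(an$sidechain_ids(1), an$sidechain_ids(3))
  expect_equal(detect_boundary_atoms(ptop, region),
               c(an$expected_sidechain_boundary(1),
                 an$expected_sidechain_boundary(3)))

  # one full interior residue cuts its two peptide bonds
  r2 <- an$residue_ids(2)
  expect_equal(detect_boundary_atoms(ptop, r2), c(r2[1], r2[3]))  # N and C

  # fully contained molecule and whole-system selections cut nothing
  expect_equal(detect_boundary_atoms(prep0$top, 1:10), integer(0))
  expect_equal(detect_boundary_atoms(ptop, seq_len(pep$n_atoms)), integer(0))

  # brute-force oracle on randomized regions
  set.seed(5)
  gb <- ptop$global_bonds
  for (i in 1:25) {
    region <- sort(sample(seq_len(pep$n_atoms), sample(1:17, 1)))
    brute <- sort(unique(unlist(lapply(region, function(a) {
      nb <- c(gb[gb[, 1] == a, 2], gb[gb[, 2] == a, 1])
      if (any(!(nb %in% region))) a else NULL
    }))))
    if (length(brute) == 0) brute <- integer(0)
    expect_equal(detect_boundary_atoms(ptop, region), brute)
  }
})

test_that("generation fills MIMIC/SYSTEM/ATOMS and preserves the template", {
  prep <- qm_add(prep0, "resname is ACT")
  tmpl <- parse_cpmd(template_cpmd_text())
  res <- generate_mimic_input(prep, fixture_pp(), template = tmpl,
                              tpr_path = "run/mimic.tpr")
  s <- res$cpmd
  expect_equal(names(s$sections), c("MIMIC", "CPMD", "DFT", "SYSTEM", "ATOMS"))
  # template sections byte-identical
  expect_identical(s$sections$CPMD, tmpl$sections$CPMD)
  expect_identical(s$sections$DFT, tmpl$sections$DFT)
  # CHARGE is the declared integer, readable via the accessor
  expect_equal(cpmd_get(s, "SYSTEM", "CHARGE"), "0")

  # species blocks partition the region
  counts <- vapply(s$sections$ATOMS, function(e)
    as.integer(trimws(e$lines[3])), 0L)
  expect_equal(sum(counts), 10L)
  ov <- mimicprep:::cpmd_overlaps(s)
  expect_equal(nrow(ov), 10L)
  expect_setequal(ov$gmx_id, 1:10)
  expect_setequal(ov$cpmd_id, 1:10)

  # index group ascending
  expect_equal(res$ndx$groups$QMatoms, 1:10)

  # generation is deterministic
  res2 <- generate_mimic_input(prep, fixture_pp(), template = tmpl,
                               tpr_path = "run/mimic.tpr")
  expect_identical(serialize_cpmd(res$cpmd), serialize_cpmd(res2$cpmd))
})

test_that("cut bonds without the boundary flag abort; with it they get their own block", {
  pep <- make_peptide_chain(3, seed = 1)
  ptop <- guess_elements(read_topology(pep$top))
  pco <- read_coordinates(pep$gro)
  prep <- preparation(ptop, pco)
  prep <- qm_add(prep, pep$annotations$sidechain_query(1))
  prep <- qm_add(prep, pep$annotations$sidechain_query(3))

  expect_error(generate_mimic_input(prep, fixture_pp()),
               "open valence", class = "mimicprep_chemistry_error")

  # cutting the CA-CB1 bonds strands 0.3 e per side chain: the charge warning
  # is part of the contract
  expect_warning(res <- generate_mimic_input(prep, fixture_pp(), boundary = TRUE),
                 "not integral")
  expect_setequal(res$boundary_ids,
                  c(pep$annotations$expected_sidechain_boundary(1),
                    pep$annotations$expected_sidechain_boundary(3)))
  blocks <- res$cpmd$sections$ATOMS
  headers <- vapply(blocks, function(e) e$lines[1], "")
  expect_true("*C_BND_MT.psp" %in% headers)
  # boundary atoms appear once, in the boundary block only
  counts <- vapply(blocks, function(e) as.integer(trimws(e$lines[3])), 0L)
  expect_equal(sum(counts), length(prep$region))
  expect_equal(counts[headers == "*C_BND_MT.psp"], 2L, ignore_attr = TRUE)
})

test_that("generation preconditions are enforced", {
  expect_error(generate_mimic_input(prep0, fixture_pp()),
               "no atoms selected", class = "mimicprep_usage_error")
  prep <- qm_add(prep0, "resname is ACT")
  nopp <- pp_info("H", "H_MT.psp", "S")
  expect_error(generate_mimic_input(prep, nopp), "element",
               class = "mimicprep_usage_error")
})
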