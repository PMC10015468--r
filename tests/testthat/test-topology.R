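test_that("molecule blocks flatten into a contiguous global atom table", {
  fx <- make_solvated_small_molecule(5, seed = 1)
  top <- read_topology(fx$top, include_dirs = fx$dir)
  ga <- top$global_atoms
  expect_equal(nrow(ga), 25)
  expect_equal(ga$id, 1:25)
  expect_equal(ga$mol_name[1:10], rep("ACT", 10))
  expect_equal(ga$mol_name[11:25], rep("SOL", 15))
  expect_equal(top$molecule_order$count, c(1L, 5L))
})

test_that("global charge sum matches an independent per-molecule summation", {
  fx <- make_solvated_small_molecule(7, seed = 3)
  top <- read_topology(fx$top, include_dirs = fx$dir)
  # hand-summed oracle from the fixture definition: both molecules neutral
  act_sum <- sum(c(0.55, -0.55, -0.3, 0.1, 0.1, 0.1, -0.3, 0.1, 0.1, 0.1))
  sol_sum <- sum(c(-0.834, 0.417, 0.417))
  expect_equal(sum(top$global_atoms$charge), 1 * act_sum + 7 * sol_sum,
               tolerance = 1e-12)
  # and per-molecule sums are zero by construction
  by_mol <- tapply(top$global_atoms$charge, top$global_atoms$mol_name, sum)
  expect_true(all(abs(by_mol) < 1e-9))
})

test_that("settles constraints surface as O-H bonds and #ifdef takes the else branch", {
  fx <- make_solvated_small_molecule(2, seed = 1)
  top <- read_topology(fx$top, include_dirs = fx$dir)
  # 9 ketone bonds + 2 settles-derived bonds per water
  expect_equal(nrow(top$global_bonds), 9 + 2 * 2)
  water_bonds <- top$global_bonds[top$global_bonds[, 1] > 10, , drop = FALSE]
  expect_setequal(water_bonds[, 2] - water_bonds[, 1], c(1, 2))

  # defining FLEXIBLE instead picks the explicit [ bonds ] branch
  flex <- read_topology(fx$top, include_dirs = fx$dir, defines = "FLEXIBLE")
  expect_equal(nrow(flex$global_bonds), 9 + 2 * 2)
})

test_that("missing charge column falls back to the type registry, then 0 with a warning", {
  d <- tempfile("chargefb")
  dir.create(d)
  writeLines(c("[ atomtypes ]",
               "ct  12.011  0.25  A  0.33  0.35",  # hx has no registry entry
               "[ moleculetype ]",
               "MOL 3",
               "[ atoms ]",
               "1 ct 1 MOL C1 1",   # no charge column
               "2 hx 1 MOL H1 2",
               "[ system ]", "t", "[ molecules ]", "MOL 1"),
             file.path(d, "m.top"))
  expect_warning(top <- read_topology(file.path(d, "m.top")), "using 0")
  expect_equal(top$global_atoms$charge, c(0.25, 0))
})

test_that("structural errors are reported with their include context", {
  d <- tempfile("toperr")
  dir.create(d)
  writeLines(c('#include "missing.itp"'), file.path(d, "a.top"))
  expect_error(read_topology(file.path(d, "a.top")), "missing.itp",
               class = "mimicprep_io_error")

  writeLines(c("[ moleculetype ]", "M 3", "[ atoms ]", "1 ct 1 M C1 1 0.0 12.0",
               "[ system ]", "t", "[ molecules ]", "OTHER 1"),
             file.path(d, "b.top"))
  expect_error(read_topology(file.path(d, "b.top")), "OTHER",
               class = "mimicprep_parse_error")

  writeLines(c("[ moleculetype ]", "M 3", "[ atoms ]", "1 ct 1 M C1 1 0.0 12.0",
               "[ moleculetype ]", "M 3", "[ atoms ]", "1 ct 1 M C1 1 0.0 12.0",
               "[ system ]", "t", "[ molecules ]", "M 1"),
             file.path(d, "c.top"))
  expect_error(read_topology(file.path(d, "c.top")), "duplicate",
               class = "mimicprep_parse_error")
})

test_that("parsing ignores comments, blank lines and repeated whitespace", {
  d <- tempfile("topws")
  dir.create(d)
  writeLines(c("; full-line comment", "",
               "[ atomtypes ]",
               "  ct    12.011   0.0   A   0.33  0.35 ; trailing",
               "[ moleculetype ]", "  M   3  ",
               "[ atoms ]", "   1   ct   1   M    C1   1  0.1  12.011",
               "", "[ system ]", "t", "[ molecules ]", "   M    2  "),
             file.path(d, "w.top"))
  top <- read_topology(file.path(d, "w.top"))
  expect_equal(nrow(top$global_atoms), 2)
  expect_equal(top$atom_types$type_name, "ct")
})
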