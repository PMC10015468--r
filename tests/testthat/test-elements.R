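test_that("element resolution follows the documented precedence", {
  # exact standard-weight match resolves by mass
  g <- mimicprep:::guess_element_one(12.011, "C1", "ca")
  expect_equal(g$element, "C")
  expect_equal(g$how, "mass")

  # without a mass, the 2-letter symbol is tried before the 1-letter one
  g <- mimicprep:::guess_element_one(NA, "CL1", "x")
  expect_equal(g$element, "Cl")

  # light masses are hydrogen isotopes
  expect_equal(mimicprep:::guess_element_one(2.014, "D1", "d")$element, "H")

  # nsa table wins over everything
  g <- mimicprep:::guess_element_one(12.011, "C1", "ca", c(ca = "Fe"))
  expect_equal(g$element, "Fe")

  # name rule falls through to the type when the name is unhelpful
  expect_equal(mimicprep:::guess_element_one(NA, "1Q", "ow")$element, "O")
})

test_that("scrambled atom names still recover the true elements via masses", {
  fx <- make_solvated_small_molecule(4, seed = 11, scramble_names = TRUE)
  top <- guess_elements(read_topology(fx$top, include_dirs = fx$dir))
  truth <- fx$annotations$true_elements[top$global_atoms$type]
  expect_equal(top$global_atoms$element, unname(truth))
})

test_that("guess_elements is idempotent and errors usefully when disabled", {
  fx <- make_solvated_small_molecule(3, seed = 2)
  top <- read_topology(fx$top, include_dirs = fx$dir)
  g1 <- guess_elements(top)
  g2 <- guess_elements(g1)
  expect_identical(g1$global_atoms, g2$global_atoms)

  expect_error(guess_elements(top, guess = FALSE),
               class = "mimicprep_chemistry_error")
  # a complete nsa table substitutes for guessing
  nsa <- fx$annotations$true_elements
  g3 <- guess_elements(top, nsa_table = as.list(nsa), guess = FALSE)
  expect_false(anyNA(g3$global_atoms$element))
})

test_that("fix_top output resolves all species with guessing disabled", {
  fx <- make_solvated_small_molecule(3, seed = 5)
  out1 <- file.path(tempfile("fixed"), "round1")
  res <- fix_top(fx$top, out1, include_dirs = fx$dir)
  fixed <- read_topology(res$top, include_dirs = dirname(res$top))
  expect_false(anyNA(fixed$global_atoms$element))
  # the Case-2 style check: no guessing, no nsa table, still complete
  expect_silent(resolved <- guess_elements(fixed, guess = FALSE))
  expect_equal(resolved$global_atoms$element,
               unname(fx$annotations$true_elements[fixed$global_atoms$type]))
})

test_that("fix_top is idempotent byte-for-byte", {
  fx <- make_solvated_small_molecule(2, seed = 8)
  base <- tempfile("fixiter")
  r1 <- fix_top(fx$top, file.path(base, "a"), include_dirs = fx$dir)
  r2 <- fix_top(r1$top, file.path(base, "b"),
                include_dirs = dirname(r1$top))
  f1 <- sort(list.files(file.path(base, "a"), recursive = TRUE))
  f2 <- sort(list.files(file.path(base, "b"), recursive = TRUE))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(base, "b", f)),
                     readLines(file.path(base, "a", f)), label = f)
})

test_that("clear_sections removes stale atomtypes; otherwise they survive verbatim", {
  fx <- make_solvated_small_molecule(2, seed = 9)
  kept <- fix_top(fx$top, tempfile("keep"), clear_sections = FALSE,
                  include_dirs = fx$dir)
  top_lines <- readLines(kept$top)
  expect_true(any(grepl("^\\[ atomtypes \\]", top_lines)) ||
              any(grepl("\\[ atomtypes \\]", top_lines)))

  cleared <- fix_top(fx$top, tempfile("clear"), clear_sections = TRUE,
                     include_dirs = fx$dir)
  for (f in cleared$files) {
    if (normalizePath(f) == normalizePath(cleared$target)) next
    expect_false(any(grepl("\\[\\s*atomtypes\\s*\\]", readLines(f))), label = f)
  }
  # the cleared output still parses and stays element-complete
  fixed <- read_topology(cleared$top, include_dirs = dirname(cleared$top))
  expect_false(anyNA(fixed$global_atoms$element))
})
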