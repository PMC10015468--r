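test_that("gro fixed-width fields are read verbatim", {
  f <- tempfile(fileext = ".gro")
  writeLines(c("one-atom system", "    1",
               "    1ACT     C1    1   1.000   2.000   3.000",
               "  5.00000   5.00000   5.00000"), f)
  cs <- read_coordinates(f)
  expect_equal(nrow(cs$atoms), 1)
  expect_equal(cs$atoms$atom_name, "C1")
  expect_equal(cs$atoms$residue_name, "ACT")
  expect_equal(cs$atoms$residue_id, 1L)
  expect_equal(unlist(cs$atoms[c("x", "y", "z")], use.names = FALSE),
               c(1, 2, 3))
  expect_equal(cs$box, c(5, 5, 5))
  expect_equal(cs$source_format, "gro")
})

test_that("xyz and GEOMETRY coordinates convert to nm", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("1", "comment", "C 10.0 0.0 0.0"), f)
  cs <- read_coordinates(f)
  expect_equal(cs$atoms$x, 1.0)
  expect_equal(cs$atoms$atom_name, "C")

  g <- file.path(tempdir(), "GEOMETRY")
  writeLines("18.897261 0.0 0.0 0.0 0.0 0.0", g)
  gs <- read_coordinates(g)
  expect_equal(gs$atoms$x, 1.0, tolerance = 1e-6)
})

test_that("pdb records carry Angstrom coordinates and the unit identity holds", {
  cs <- coordinate_set(data.frame(
    serial = 1L, atom_name = "C1", residue_name = "ACT", residue_id = 1L,
    chain_or_mol = "A", x = 1, y = 2, z = 3))
  f <- tempfile(fileext = ".pdb")
  write_coordinates(cs, f, "pdb")
  line <- grep("^ATOM", readLines(f), value = TRUE)
  expect_match(line, "10\\.000  20\\.000  30\\.000")
  back <- read_coordinates(f)
  expect_equal(back$atoms$x, 1)
  expect_equal(back$atoms$chain_or_mol, "A")

  # GEOMETRY writes Bohr: one Bohr radius in nm comes back as 1.0 Bohr
  bohr <- coordinate_set(data.frame(
    serial = 1L, atom_name = "X", residue_name = "MOL", residue_id = 1L,
    chain_or_mol = "", x = 0.0529177210903, y = 0, z = 0))
  g <- tempfile()
  write_coordinates(bohr, g, "cpmd_geometry")
  first <- as.numeric(strsplit(trimws(readLines(g)[1]), "\\s+")[[1]][1])
  expect_equal(first, 1.0, tolerance = 1e-10)
})

test_that("read-write-read is the identity within each format's precision", {
  set.seed(42)
  for (n in c(1, 17, 250, 1000)) {
    cs <- random_coordinate_set(n, with_chain = TRUE)
    for (fmt in c("gro", "pdb", "xyz", "cpmd_geometry")) {
      f <- tempfile()
      write_coordinates(cs, f, fmt)
      r1 <- read_coordinates(f, format = fmt)
      f2 <- tempfile()
      write_coordinates(r1, f2, fmt)
      r2 <- read_coordinates(f2, format = fmt)
      expect_identical(r1$atoms, r2$atoms, label = paste(fmt, n))
      tol_nm <- if (fmt == "cpmd_geometry") 1e-6 * 0.0529177 else 1e-3
      expect_lt(max(abs(as.matrix(r1$atoms[c("x", "y", "z")]) -
                        as.matrix(cs$atoms[c("x", "y", "z")]))), tol_nm)
      if (fmt %in% c("gro", "pdb"))
        expect_identical(r1$atoms$atom_name, cs$atoms$atom_name)
    }
  }
})

test_that("unit conversions compose across formats", {
  set.seed(7)
  cs <- random_coordinate_set(50)
  pdb <- tempfile(fileext = ".pdb")
  write_coordinates(cs, pdb, "pdb")
  from_pdb <- read_coordinates(pdb)
  gro <- tempfile(fileext = ".gro")
  write_coordinates(from_pdb, gro, "gro")
  from_gro <- read_coordinates(gro)
  expect_lt(max(abs(as.matrix(from_gro$atoms[c("x", "y", "z")]) -
                    as.matrix(from_pdb$atoms[c("x", "y", "z")]))), 1e-3)
})

test_that("malformed input and misuse raise informative errors", {
  expect_error(read_coordinates(tempfile()), class = "mimicprep_io_error")

  bad <- tempfile(fileext = ".gro")
  writeLines(c("t", "    1", "    1ACT     C1    1   x.000   2.000   3.000",
               "  5.0 5.0 5.0"), bad)
  expect_error(read_coordinates(bad), "line 3", class = "mimicprep_parse_error")

  unknown <- tempfile(fileext = ".foo")
  file.create(unknown)
  expect_error(read_coordinates(unknown), class = "mimicprep_usage_error")

  empty <- coordinate_set(data.frame(
    serial = 1L, atom_name = "C", residue_name = "M", residue_id = 1L,
    chain_or_mol = "", x = 0, y = 0, z = 0))
  empty$atoms <- empty$atoms[0, ]
  out <- tempfile()
  expect_error(write_coordinates(empty, out, "gro"),
               class = "mimicprep_usage_error")
  expect_false(file.exists(out))
})

test_that("gro output without a box synthesizes one with a warning", {
  cs <- random_coordinate_set(5, with_box = FALSE)
  f <- tempfile(fileext = ".gro")
  expect_warning(write_coordinates(cs, f, "gro"), "margin")
  back <- read_coordinates(f)
  expect_true(all(back$box > 0))
})
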