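# Shared builders and independent oracles used across the suite.

# pp table covering the fixture elements, with boundary pseudopotentials for
# the elements that can sit on a cut bond.
fixture_pp <- function() {
  pp_info(element = c("H", "C", "N", "O"),
          pp_filename = c("H_MT_BLYP.psp", "C_MT_BLYP.psp",
                          "N_MT_BLYP.psp", "O_MT_BLYP.psp"),
          lmax = c("S", "P", "P", "P"),
          loc = c(NA, "P", "P", "P"),
          boundary_filename = c(NA, "C_BND_MT.psp", "N_BND_MT.psp", NA))
}

write_fixture_pp <- function(path = tempfile(fileext = ".dat")) {
  write_pp_info(fixture_pp(), path)
  path
}

template_cpmd_text <- function() {
  c("&CPMD",
    "ANNEAL IONS",
    "TIMESTEP",
    "    5.0",
    "&END",
    "&DFT",
    "FUNCTIONAL BLYP",
    "&END")
}

write_template_cpmd <- function(path = tempfile(fileext = ".inp")) {
  writeLines(template_cpmd_text(), path)
  path
}

write_template_mdp <- function(path = tempfile(fileext = ".mdp")) {
  writeLines(c("; generic MD parameters",
               "dt          = 0.002  ; ps",
               "nsteps      = 5000",
               "",
               "tcoupl      = v-rescale"), path)
  path
}

# Row-by-row brute-force evaluation of a selection AST: the oracle against
# which evaluate_selection is checked. Deliberately scalar and independent
# of the vectorized implementation.
brute_row_table <- function(top) {
  ga <- top$global_atoms
  data.frame(id = ga$id, name = ga$name, type = ga$type, resid = ga$resid,
             resname = ga$resname, mol = ga$mol_name, stringsAsFactors = FALSE)
}

brute_predicate <- function(node, row) {
  if (node$kind == "cmp") {
    v <- row[[node$keyword]]
    return(switch(node$op,
      "is" = v == node$value, "not" = v != node$value,
      ">" = v > node$value, "<" = v < node$value,
      ">=" = v >= node$value, "<=" = v <= node$value))
  }
  if (node$kind == "not") return(!brute_predicate(node$arg, row))
  if (node$kind == "and")
    return(brute_predicate(node$lhs, row) && brute_predicate(node$rhs, row))
  if (node$kind == "or")
    return(brute_predicate(node$lhs, row) || brute_predicate(node$rhs, row))
  stop("unknown node kind")
}

brute_select <- function(ast, top) {
  tab <- brute_row_table(top)
  keep <- vapply(seq_len(nrow(tab)), function(i)
    brute_predicate(ast, tab[i, , drop = FALSE]), logical(1))
  sort(tab$id[keep])
}

# Random query-text generator (depth-bounded), biased toward literals that
# actually occur in the fixtures plus a few misses.
random_query_text <- function(depth = 4) {
  str_kw <- c("resname", "name", "type", "mol")
  str_pool <- c("ACT", "SOL", "RES", "OW", "HW1", "C1", "CB1", "c_me", "ow",
                "PEP", "ZZZ")
  comparison <- function() {
    if (stats::runif(1) < 0.4) {
      kw <- sample(c("id", "resid"), 1)
      op <- sample(c("is", "not", ">", "<", ">=", "<="), 1)
      sprintf("%s %s %d", kw, op, sample(0:30, 1))
    } else {
      sprintf("%s %s %s", sample(str_kw, 1), sample(c("is", "not"), 1),
              sample(str_pool, 1))
    }
  }
  gen <- function(d) {
    if (d <= 0 || stats::runif(1) < 0.35) return(comparison())
    switch(sample(c("and", "or", "not", "group"), 1),
      and = paste(gen(d - 1), "and", gen(d - 1)),
      or = paste(gen(d - 1), "or", gen(d - 1)),
      not = paste("not", gen(d - 1)),
      group = paste0("( ", gen(d - 1), " )"))
  }
  gen(depth)
}

# Random coordinate sets for round-trip properties: names and ids sized to
# fit every format's fixed-width fields.
random_coordinate_set <- function(n, with_box = TRUE, with_chain = FALSE) {
  names_pool <- c("C1", "CA", "OW", "HW1", "N", "CB2", "O2", "H11")
  res_pool <- c("ACT", "SOL", "RES", "ALA")
  atoms <- data.frame(
    serial = seq_len(n),
    atom_name = sample(names_pool, n, replace = TRUE),
    residue_name = sample(res_pool, n, replace = TRUE),
    residue_id = sort(sample(1:999, n, replace = TRUE)),
    chain_or_mol = if (with_chain) sample(c("A", "B"), n, replace = TRUE) else "",
    x = round(stats::runif(n, 0, 9), 4),
    y = round(stats::runif(n, 0, 9), 4),
    z = round(stats::runif(n, 0, 9), 4),
    stringsAsFactors = FALSE)
  coordinate_set(atoms, box = if (with_box) c(10, 10, 10))
}

# Acetone-in-water preparation, ready for generation.
fixture_preparation <- function(n_waters = 5, seed = 1,
                                dir = tempfile("prepfx")) {
  fx <- make_solvated_small_molecule(n_waters, seed = seed, dir = dir)
  top <- guess_elements(read_topology(fx$top, include_dirs = fx$dir))
  prep <- preparation(top, read_coordinates(fx$gro))
  list(fx = fx, prep = prep)
}
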