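fx_sel <- make_solvated_small_molecule(5, seed = 1)
top_sel <- read_topology(fx_sel$top, include_dirs = fx_sel$dir)

test_that("the grammar parses the documented query forms", {
  q <- parse_query("resname is ACT")
  expect_equal(q$kind, "cmp")
  expect_equal(q$keyword, "resname")
  expect_equal(q$op, "is")
  expect_equal(q$value, "ACT")

  q <- parse_query("(resid is 100 or resid is 109) and not name is CA")
  expect_equal(q$kind, "and")
  expect_equal(q$lhs$kind, "or")
  expect_equal(q$rhs$kind, "not")
  expect_equal(q$rhs$arg$kind, "cmp")
  expect_equal(q$lhs$lhs$value, 100L)

  # unicode operators and case-insensitive keywords
  q <- parse_query("ID ≥ 3 AND Id ≤ 5")
  expect_equal(q$lhs$op, ">=")
  expect_equal(q$rhs$op, "<=")

  # "not" as a comparison operator after a keyword
  q <- parse_query("name not CA")
  expect_equal(q$op, "not")
})

test_that("malformed queries fail with a character position", {
  expect_error(parse_query("resname ACT"), "character 9",
               class = "mimicprep_parse_error")
  expect_error(parse_query("color is red"), "unknown keyword",
               class = "mimicprep_parse_error")
  expect_error(parse_query("resname is"), "dangling",
               class = "mimicprep_parse_error")
  expect_error(parse_query("(resname is ACT"), "unbalanced",
               class = "mimicprep_parse_error")
  expect_error(parse_query("name > CA"), "only to id/resid",
               class = "mimicprep_parse_error")
  expect_error(parse_query("resid is ACT"), "integer",
               class = "mimicprep_parse_error")
})

test_that("evaluation implements set semantics on the global atom table", {
  expect_equal(evaluate_selection("id > 3 and id <= 5", top_sel), c(4L, 5L))
  expect_equal(evaluate_selection("resname is ACT or resname is SOL", top_sel),
               1:25)
  expect_equal(evaluate_selection("resname is ACT", top_sel), 1:10)
  expect_equal(evaluate_selection("mol is SOL", top_sel), 11:25)
  expect_equal(evaluate_selection("name is OW", top_sel),
               seq(11L, 23L, by = 3L))
})

test_that("operator precedence binds and tighter than or", {
  a <- evaluate_selection("resname is SOL or resname is ACT and id < 3", top_sel)
  b <- evaluate_selection("resname is SOL or (resname is ACT and id < 3)", top_sel)
  c_ <- evaluate_selection("(resname is SOL or resname is ACT) and id < 3", top_sel)
  expect_equal(a, b)
  expect_false(identical(a, c_))
})

test_that("random queries agree with the brute-force row predicate", {
  set.seed(2024)
  n_agree <- 0L
  for (i in 1:200) {
    text <- random_query_text(4)
    ast <- parse_query(text)
    expect_equal(evaluate_selection(ast, top_sel), brute_select(ast, top_sel),
                 label = text)
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 200L)
})

test_that("boolean identities hold on sampled expressions", {
  set.seed(99)
  all_ids <- top_sel$global_atoms$id
  for (i in 1:40) {
    x <- random_query_text(2)
    y <- random_query_text(2)
    ex <- evaluate_selection(x, top_sel)
    ey <- evaluate_selection(y, top_sel)
    expect_equal(evaluate_selection(paste0("not ( ", x, " )"), top_sel),
                 setdiff(all_ids, ex))
    expect_equal(
      evaluate_selection(paste0("( ", x, " ) and ( ", y, " )"), top_sel),
      intersect(ex, ey))
    expect_equal(evaluate_selection(paste(x, "or", y), top_sel),
                 sort(union(ex, ey)))
    # De Morgan
    expect_equal(
      evaluate_selection(paste0("not ( ( ", x, " ) and ( ", y, " ) )"), top_sel),
      sort(union(setdiff(all_ids, ex), setdiff(all_ids, ey))))
  }
})
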