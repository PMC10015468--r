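# The atom-selection query language. Queries select atoms by residue name
# (resname), residue ID (resid), atom name (name), atom type (type), atom ID
# (id) or molecule/chain (mol), combined with and/or/not and brackets:
#
#   expr       := term ("or" term)*
#   term       := factor ("and" factor)*
#   factor     := "not" factor | "(" expr ")" | comparison
#   comparison := keyword operator literal
#
# Comparison operators are is, not, >, <, >=, <= (Unicode >= and <= accepted).
# Ordering operators apply only to the integer fields id and resid; names and
# ids follow the conventions of the GROMACS topology. Keywords and operators
# are case-insensitive, literals case-sensitive. Operator precedence is
# comparison > not > and > or. "not" is both a comparison operator
# ("name not CA") and a unary prefix ("not name is CA"), disambiguated by
# position: directly after a keyword it is the comparison operator.

SEL_KEYWORDS <- c("resname", "resid", "name", "type", "id", "mol")
SEL_INT_KEYWORDS <- c("resid", "id")
SEL_ORDER_OPS <- c(">", "<", ">=", "<=")

sel_tokenize <- function(text) {
  text <- gsub("≥", ">=", gsub("≤", "<=", text))
  m <- gregexpr("\\(|\\)|>=|<=|[^\\s()]+", text, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(text = character(), pos = integer()))
  data.frame(text = regmatches(text, list(m))[[1]], pos = as.integer(m),
             stringsAsFactors = FALSE)
}

#' Parse a selection query
#'
#' Parses the selection language into an expression tree. See the grammar in
#' the package vignette; examples: `"resname is ACT"`,
#' `"(resid is 100 or resid is 109) and not name is CA"`.
#'
#' @param text a nonempty query string.
#' @return an object of class `mimic_query` (a nested list of `cmp`, `and`,
#'   `or`, `not` nodes).
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop_usage("selection query must be a nonempty string")
  st <- new.env(parent = emptyenv())
  st$tok <- sel_tokenize(text)
  st$i <- 1L
  peek <- function() if (st$i <= nrow(st$tok)) st$tok$text[st$i] else NA_character_
  pos <- function() if (st$i <= nrow(st$tok)) st$tok$pos[st$i] else nchar(text) + 1L
  advance <- function() { v <- peek(); st$i <- st$i + 1L; v }
  fail <- function(msg, at = pos())
    stop_parse(sprintf("selection parse error at character %d: %s", at, msg))

  parse_comparison <- function() {
    kw_pos <- pos()
    kw <- tolower(advance())
    if (is.na(kw) || !(kw %in% SEL_KEYWORDS))
      fail(sprintf("unknown keyword '%s'", kw), kw_pos)
    op_pos <- pos()
    op_raw <- advance()
    if (is.na(op_raw)) fail("dangling keyword: expected an operator", op_pos)
    op <- tolower(op_raw)
    if (!(op %in% c("is", "not", SEL_ORDER_OPS)))
      fail(sprintf("expected an operator (is/not/>/</>=/<=), got '%s'", op_raw),
           op_pos)
    if (op %in% SEL_ORDER_OPS && !(kw %in% SEL_INT_KEYWORDS))
      fail(sprintf("ordering operator '%s' applies only to id/resid", op), op_pos)
    lit_pos <- pos()
    lit <- advance()
    if (is.na(lit) || lit %in% c("(", ")"))
      fail("dangling operator: expected a literal", lit_pos)
    if (kw %in% SEL_INT_KEYWORDS) {
      if (!grepl("^-?[0-9]+$", lit))
        fail(sprintf("'%s' requires an integer literal, got '%s'", kw, lit),
             lit_pos)
      lit <- as.integer(lit)
    }
    list(kind = "cmp", keyword = kw, op = op, value = lit)
  }

  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of query")
    if (tolower(t) == "not") {
      st$i <- st$i + 1L
      return(list(kind = "not", arg = parse_factor()))
    }
    if (t == "(") {
      open_pos <- pos()
      st$i <- st$i + 1L
      inner <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        fail("unbalanced brackets: missing ')'", open_pos)
      st$i <- st$i + 1L
      return(inner)
    }
    parse_comparison()
  }

  parse_term <- function() {
    node <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      st$i <- st$i + 1L
      node <- list(kind = "and", lhs = node, rhs = parse_factor())
    }
    node
  }

  parse_expr <- function() {
    node <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      st$i <- st$i + 1L
      node <- list(kind = "or", lhs = node, rhs = parse_term())
    }
    node
  }

  ast <- parse_expr()
  if (!is.na(peek()))
    fail(sprintf("unexpected token '%s'", peek()))
  structure(ast, class = "mimic_query", query = text)
}

#' @export
print.mimic_query <- function(x, ...) {
  cat("<mimic_query>", attr(x, "query"), "\n")
  invisible(x)
}

selection_atom_table <- function(x) {
  if (inherits(x, "topology")) {
    ga <- x$global_atoms
    data.frame(id = ga$id, name = ga$name, type = ga$type, resid = ga$resid,
               resname = ga$resname, mol = ga$mol_name,
               stringsAsFactors = FALSE)
  } else if (inherits(x, "coordinate_set")) {
    # coordinate-only systems: mol matches the chain ID, type is unavailable
    a <- x$atoms
    data.frame(id = a$serial, name = a$atom_name, type = "",
               resid = a$residue_id, resname = a$residue_name,
               mol = a$chain_or_mol, stringsAsFactors = FALSE)
  } else {
    stop_usage("selections evaluate against a topology or a coordinate_set")
  }
}

eval_query_mask <- function(node, tab) {
  switch(node$kind,
    cmp = {
      field <- tab[[node$keyword]]
      switch(node$op,
        "is" = field == node$value,
        "not" = field != node$value,
        ">" = field > node$value,
        "<" = field < node$value,
        ">=" = field >= node$value,
        "<=" = field <= node$value)
    },
    "not" = !eval_query_mask(node$arg, tab),
    "and" = eval_query_mask(node$lhs, tab) & eval_query_mask(node$rhs, tab),
    "or" = eval_query_mask(node$lhs, tab) | eval_query_mask(node$rhs, tab),
    stop_usage(paste0("unknown query node kind: ", node$kind)))
}

#' Evaluate a selection against a system
#'
#' @param ast a [parse_query()] result (a plain query string is accepted and
#'   parsed on the fly).
#' @param system a `topology` (usual case) or a `coordinate_set` (then `mol`
#'   matches the chain ID and `type` selects nothing).
#' @return ascending integer vector of global atom ids.
#' @export
evaluate_selection <- function(ast, system) {
  if (is.character(ast)) ast <- parse_query(ast)
  tab <- selection_atom_table(system)
  sort(tab$id[eval_query_mask(ast, tab)])
}
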