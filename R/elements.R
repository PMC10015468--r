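# Atomic-species inference. Force fields frequently omit element information
# for nonstandard molecules (ligands, cofactors); CPMD needs it for every QM
# atom and the index map needs it for every atom. Elements are resolved per
# atom in a fixed precedence:
#   1. a user-supplied nonstandard-species table (atom type -> element),
#   2. mass: nearest standard atomic weight within +/- 0.5 amu among elements
#      1-86 (masses below 3.5 amu are hydrogen isotopes -> H),
#   3. the leading alphabetic characters of the atom name, tried as a
#      two-letter then a one-letter element symbol,
#   4. the same procedure applied to the atom type.
# Mass ties and atoms that fall through every rule are reported.

periodic_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- bio3d::elements
      e <- e[e$num >= 1 & e$num <= 86, c("num", "symb", "mass")]
      e$symb <- as.character(e$symb)
      cache <<- e
    }
    cache
  }
})

element_from_z <- function(z) {
  pt <- periodic_table()
  pt$symb[match(z, pt$num)]
}

element_z <- function(symbol) {
  pt <- periodic_table()
  pt$num[match(symbol, pt$symb)]
}

normalize_element <- function(symbol) {
  # IUPAC capitalization regardless of input case
  s <- tolower(symbol)
  out <- paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  ifelse(out %in% periodic_table()$symb, out, NA_character_)
}

element_by_mass <- function(mass) {
  if (is.na(mass) || mass <= 0) return(list(element = NA_character_, tie = FALSE))
  if (mass < 3.5) return(list(element = "H", tie = FALSE))
  pt <- periodic_table()
  d <- abs(pt$mass - mass)
  i <- which(d <= 0.5)
  if (length(i) == 0) return(list(element = NA_character_, tie = FALSE))
  best <- i[order(d[i])]
  if (length(best) > 1 && abs(d[best[1]] - d[best[2]]) < 1e-9)
    return(list(element = NA_character_, tie = TRUE))
  list(element = pt$symb[best[1]], tie = FALSE)
}

element_by_label <- function(label) {
  if (is.na(label) || !grepl("^[A-Za-z]", label)) return(NA_character_)
  lead <- toupper(sub("^([A-Za-z]+).*$", "\\1", label))
  if (nchar(lead) >= 2) {
    two <- normalize_element(substr(lead, 1, 2))
    if (!is.na(two)) return(two)
  }
  one <- normalize_element(substr(lead, 1, 1))
  one
}

guess_element_one <- function(mass, name, type, nsa_table = NULL) {
  if (!is.null(nsa_table) && type %in% names(nsa_table)) {
    el <- normalize_element(nsa_table[[type]])
    if (is.na(el))
      stop_usage(paste0("nonstandard-species table maps type '", type,
                        "' to unknown element '", nsa_table[[type]], "'"))
    return(list(element = el, how = "nsa", note = NA_character_))
  }
  bm <- element_by_mass(mass)
  if (!is.na(bm$element))
    return(list(element = bm$element, how = "mass", note = NA_character_))
  note <- if (bm$tie) sprintf("mass %.3f amu is equidistant from two elements", mass)
          else NA_character_
  el <- element_by_label(name)
  if (!is.na(el)) return(list(element = el, how = "name", note = note))
  el <- element_by_label(type)
  if (!is.na(el)) return(list(element = el, how = "type", note = note))
  list(element = NA_character_, how = "failed", note = note)
}

#' Infer missing atomic elements in a topology
#'
#' Fills the `element` column of the global atom table (and the atom-type
#' registry, where all atoms of a type agree). Atoms that already carry an
#' element — e.g. from an `at.num` column in `[ atomtypes ]` — are left
#' untouched, which makes the operation idempotent.
#'
#' Resolution order per atom: the `nsa_table` entry for its type; the mass
#' rule (nearest standard atomic weight within 0.5 amu among elements 1–86,
#' masses below 3.5 amu resolving to H); the leading alphabetic characters of
#' the atom name as a two-letter then one-letter symbol; the same on the atom
#' type. Mass ties and unresolvable atoms are collected in the
#' `guess_report` attribute.
#'
#' @param top a [read_topology()] result.
#' @param nsa_table optional named character vector / list mapping atom-type
#'   names to element symbols (the `-nsa` table).
#' @param guess if `FALSE`, only `nsa_table` (and pre-existing elements) may
#'   resolve species; any atom left unresolved raises an error listing the
#'   offending types.
#' @return the topology with every global atom assigned an element.
#' @export
guess_elements <- function(top, nsa_table = NULL, guess = TRUE) {
  ga <- top$global_atoms
  todo <- is.na(ga$element)
  if (!any(todo)) return(top)
  key <- paste(ga$type[todo], ga$name[todo], ga$mass[todo], sep = "\r")
  uniq <- !duplicated(key)
  uniq_idx <- which(todo)[uniq]
  notes <- character(0)
  results <- vapply(uniq_idx, function(i) {
    if (!guess) {
      if (!is.null(nsa_table) && ga$type[i] %in% names(nsa_table)) {
        el <- normalize_element(nsa_table[[ga$type[i]]])
        return(if (is.na(el)) NA_character_ else el)
      }
      return(NA_character_)
    }
    g <- guess_element_one(ga$mass[i], ga$name[i], ga$type[i], nsa_table)
    if (!is.na(g$note))
      notes <<- c(notes, sprintf("%s (%s): %s", ga$name[i], ga$type[i], g$note))
    g$element
  }, character(1))
  ga$element[todo] <- results[match(key, key[uniq])]

  unresolved <- unique(ga$type[is.na(ga$element)])
  if (length(unresolved) > 0) {
    if (!guess)
      stop_chem(paste0("element guessing is disabled and the species of ",
                       "type(s) ", paste(unresolved, collapse = ", "),
                       " cannot be resolved; supply them via an nsa table"))
    stop_chem(paste0("could not infer the element of atom type(s): ",
                     paste(unresolved, collapse = ", ")))
  }
  if (length(notes) > 0)
    warning(paste0("element guessing fell back past the mass rule for: ",
                   paste(unique(notes), collapse = "; ")), call. = FALSE)

  top$global_atoms <- ga
  # propagate to the registry where unambiguous
  per_type <- tapply(ga$element, ga$type, function(e) {
    u <- unique(e); if (length(u) == 1) u else NA_character_
  })
  j <- match(names(per_type), top$atom_types$type_name)
  fill <- !is.na(j) & is.na(top$atom_types$element[j]) & !is.na(per_type)
  top$atom_types$element[j[fill]] <- per_type[fill]
  top$atom_types$at_num[j[fill]] <- element_z(per_type[fill])
  # and to the per-moleculetype tables
  for (nm in names(top$moltypes)) {
    mt <- top$moltypes[[nm]]
    rows <- which(ga$mol_name == nm)[seq_len(nrow(mt$atoms))]
    top$moltypes[[nm]]$atoms$element <- ga$element[rows]
  }
  attr(top, "guess_report") <- notes
  top
}
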