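#' Parse a molecular formula
#'
#' Parses a plain-concatenation composition string ("H2SO4", "Fe2O3") into a
#' composition map. Symbols are matched case-sensitively against the element
#' registry; duplicated symbols are merged by adding their coefficients
#' ("OO" is O2). Coefficients may be positive integers or rationals written
#' `p/q` ("O7/3"), the latter arising when formulae rescaled to a historical
#' atomic-weight system are round-tripped through text. Coefficients are held
#' as exact reduced rationals so rescaling never loses precision.
#'
#' @param text a single composition string.
#' @return an object of class `chem_formula`: a list with character vector
#'   `symbol` (lexicographically sorted) and numeric vectors `num`, `den`
#'   (reduced coefficient numerators/denominators).
#' @examples
#' parse_formula("H2SO4")
#' render_formula(parse_formula("OO"))  # "O2"
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    .stopf("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]+(?:/[0-9]+)?)?", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]+(?:/[0-9]+)?)?", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) covered[m[i] + seq_len(attr(m, "match.length")[i]) - 1L] <- TRUE
    bad <- substr(text, which(!covered)[1], which(!covered)[1])
    .stopf("cannot parse formula '%s': unexpected token '%s'", text, bad)
  }
  sym <- sub("^([A-Z][a-z]?).*$", "\\1", toks)
  coef <- sub("^[A-Z][a-z]?", "", toks)
  unknown <- sym[!is_element_symbol(sym)]
  if (length(unknown) > 0)
    .stopf("unknown element symbol '%s' in formula '%s'", unknown[1], text)
  num <- den <- numeric(length(sym))
  for (i in seq_along(sym)) {
    if (!nzchar(coef[i])) { num[i] <- 1; den[i] <- 1 }
    else if (grepl("/", coef[i], fixed = TRUE)) {
      pq <- as.numeric(strsplit(coef[i], "/", fixed = TRUE)[[1]])
      if (pq[2] == 0) .stopf("zero denominator in coefficient of '%s'", text)
      r <- .rat(pq[1], pq[2]); num[i] <- r$num; den[i] <- r$den
    } else { num[i] <- as.numeric(coef[i]); den[i] <- 1 }
    if (num[i] <= 0) .stopf("non-positive coefficient in formula '%s'", text)
  }
  # merge duplicate symbols by rational addition
  if (anyDuplicated(sym)) {
    us <- unique(sym)
    nn <- dd <- numeric(length(us))
    for (i in seq_along(us)) {
      idx <- which(sym == us[i])
      acc <- .rat(0, 1)
      for (j in idx) acc <- .rat_add(acc, .rat(num[j], den[j]))
      nn[i] <- acc$num; dd[i] <- acc$den
    }
    sym <- us; num <- nn; den <- dd
  }
  o <- order(sym)
  structure(list(symbol = sym[o], num = num[o], den = den[o]),
            class = "chem_formula")
}

.coef_chr <- function(num, den) {
  ifelse(num == 1 & den == 1, "",
         ifelse(den == 1, as.character(num), paste0(num, "/", den)))
}

#' Render a formula canonically
#'
#' Canonical text: symbols in lexicographic order, coefficient 1 omitted,
#' rational coefficients rendered `p/q`.
#'
#' @param f a `chem_formula`.
#' @return a character scalar.
#' @export
render_formula <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  o <- order(f$symbol)
  paste0(f$symbol[o], .coef_chr(f$num[o], f$den[o]), collapse = "")
}

#' @export
format.chem_formula <- function(x, ...) render_formula(x)

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", render_formula(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.chem_formula` <- function(e1, e2) render_formula(e1) == render_formula(e2)

#' Element combination of a formula
#'
#' The set of elements present in a formula irrespective of coefficients,
#' rendered as the lexicographic concatenation of symbols: the combination of
#' H2SO4 is "HOS". Combinations are the coarse unit in which the growth and
#' diversity of the chemical space is tracked.
#'
#' @param f a `chem_formula` or a formula string.
#' @return a character scalar.
#' @examples
#' combination_of("H2SO4")  # "HOS"
#' @export
combination_of <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  paste(sort(f$symbol), collapse = "")
}

#' Arranged formula: replace one element by the placeholder X
#'
#' Produces the arranged formula of `f` with respect to element `element`: the
#' canonical rendering in which that element's symbol is replaced by the
#' placeholder "X" and all symbols (including X) are re-sorted
#' lexicographically, coefficients preserved. Arranged formulae are compared
#' only for string equality; "X" sorts as the literal letter X. They are the
#' unit of the substitutability similarity between elements.
#'
#' @param f a `chem_formula` or formula string.
#' @param element the element symbol to substitute; must occur in `f`.
#' @return a character scalar, e.g. `arrange_formula("C2H2Br2", "Br")` is
#'   `"C2H2X2"`.
#' @export
arrange_formula <- function(f, element) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  if (!element %in% f$symbol)
    .stopf("element '%s' does not occur in formula '%s'", element, render_formula(f))
  sym <- f$symbol
  sym[sym == element] <- "X"
  o <- order(sym)
  paste0(sym[o], .coef_chr(f$num[o], f$den[o]), collapse = "")
}

#' Undo an arranged-formula substitution
#'
#' Substitutes `element` back for the placeholder X in an arranged-formula
#' string and re-canonicalizes, recovering the original formula rendering.
#'
#' @param arranged an arranged-formula string containing exactly one X token.
#' @param element the element to restore.
#' @return the canonical formula string.
#' @export
unarrange_formula <- function(arranged, element) {
  if (!grepl("X", arranged, fixed = TRUE))
    .stopf("'%s' contains no placeholder X", arranged)
  restored <- gsub("X(?![a-z])", element, arranged, perl = TRUE)
  render_formula(parse_formula(restored))
}
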