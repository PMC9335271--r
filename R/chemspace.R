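#' Year-indexed cumulative chemical space
#'
#' A chemical space is the cumulative collection of known substances up to a
#' given year. Each substance carries an opaque identifier, a composition
#' formula, and the calendar year it was first reported. The constructor
#' parses every formula once, canonicalizes it, derives its element
#' combination, and precomputes the table of arranged formulae (one row per
#' substance x contained element) that drives all similarity computations.
#'
#' Distinct substances with identical formulae (isomers, allotropes,
#' polymorphs) are distinct records and are never deduplicated: this is what
#' makes per-element arranged-formula collections multisets.
#'
#' @param substances a data.frame with columns `id`, `formula`, `year`.
#' @param window optional integer vector `c(first_year, last_year)`; defaults
#'   to the range of `year`.
#' @return an object of class `chemical_space` with elements `substances`
#'   (data.table: id, formula, year, combination, comb_size), `tokens`
#'   (id, symbol, num, den), `arranged` (id, element, arranged) and `window`.
#' @examples
#' sp <- chemical_space(data.frame(
#'   id = c("s1", "s2", "s3"),
#'   formula = c("H2O", "H2O2", "NaCl"),
#'   year = c(1800, 1815, 1807)))
#' n_substances(sp)
#' @export
chemical_space <- function(substances, window = NULL) {
  stopifnot(is.data.frame(substances))
  need <- c("id", "formula", "year")
  if (!all(need %in% names(substances)))
    .stopf("substance table must have columns id, formula, year")
  dt <- data.table::as.data.table(substances)[, .SD, .SDcols = need]
  dt[, `:=`(id = as.character(id), formula = as.character(formula),
            year = as.integer(year))]
  if (anyDuplicated(dt$id)) .stopf("substance ids must be unique")
  if (anyNA(dt$year)) .stopf("substance years must be integers")
  if (is.null(window)) window <- range(dt$year)
  window <- as.integer(window)
  if (any(dt$year < window[1] | dt$year > window[2]))
    .stopf("substance years fall outside the study window [%d, %d]",
           window[1], window[2])

  # parse each distinct formula once
  uf <- unique(dt$formula)
  parsed <- lapply(uf, parse_formula)
  names(parsed) <- uf
  canon <- vapply(parsed, render_formula, character(1))
  dt[, formula := canon[formula]]

  tok <- data.table::rbindlist(lapply(seq_along(uf), function(i) {
    p <- parsed[[i]]
    data.table::data.table(formula = canon[i], symbol = p$symbol,
                           num = p$num, den = p$den)
  }))
  tokens <- merge(dt[, .(id, formula)], tok, by = "formula",
                  allow.cartesian = TRUE)[, .(id, symbol, num, den)]

  comb <- tokens[, .(combination = paste(sort(symbol), collapse = ""),
                     comb_size = .N), by = id]
  dt <- merge(dt, comb, by = "id")

  arranged <- .build_arranged(tokens)

  structure(list(substances = dt[order(year, id)],
                 tokens = tokens,
                 arranged = arranged,
                 window = window),
            class = "chemical_space")
}

# one row per (substance, element-of-substance): the arranged formula string
.build_arranged <- function(tokens) {
  slots <- tokens[, .(id, element = symbol)]
  x <- merge(slots, tokens, by = "id", allow.cartesian = TRUE)
  x[, sym2 := ifelse(symbol == element, "X", symbol)]
  x[, piece := paste0(sym2, .coef_chr(num, den))]
  data.table::setorder(x, id, element, sym2)
  x[, .(arranged = paste(piece, collapse = "")), by = .(id, element)]
}

#' @export
print.chemical_space <- function(x, ...) {
  cat(sprintf("<chemical_space> %d substances, %d elements, window [%d, %d]\n",
              nrow(x$substances), length(unique(x$tokens$symbol)),
              x$window[1], x$window[2]))
  invisible(x)
}

#' @rdname chemical_space
#' @param space a `chemical_space`.
#' @export
n_substances <- function(space) nrow(space$substances)

#' Cumulative snapshot of a chemical space
#'
#' Restricts the space to substances first reported up to `year` (inclusive).
#' Snapshots are cumulative: `snapshot(sp, y1)` is contained in
#' `snapshot(sp, y2)` whenever `y1 <= y2`.
#'
#' @param space a `chemical_space`.
#' @param year a year within the space's window.
#' @return a `chemical_space`.
#' @export
snapshot <- function(space, year) {
  stopifnot(inherits(space, "chemical_space"))
  year <- as.integer(year)
  if (year < space$window[1] || year > space$window[2])
    .stopf("year %d outside the study window [%d, %d]", year,
           space$window[1], space$window[2])
  keep <- space$substances$id[space$substances$year <= year]
  structure(list(substances = space$substances[id %in% keep],
                 tokens = space$tokens[id %in% keep],
                 arranged = space$arranged[id %in% keep],
                 window = c(space$window[1], year)),
            class = "chemical_space")
}

#' Elements known at a given year
#'
#' By default an element is "known" once it occurs in any substance of the
#' snapshot (computable from the data alone). A discovery-year table, when
#' supplied, overrides occurrence: it reflects external scholarship on when
#' elements were actually discovered, which may precede their first appearance
#' in a compound.
#'
#' @param space a `chemical_space`.
#' @param year snapshot year.
#' @param discovery optional named numeric vector (element -> discovery year)
#'   or data.frame with columns `element`, `year`.
#' @return character vector of element symbols, sorted.
#' @export
elements_known <- function(space, year, discovery = NULL) {
  stopifnot(inherits(space, "chemical_space"))
  if (!is.null(discovery)) {
    if (is.data.frame(discovery)) {
      dy <- discovery$year
      names(dy) <- discovery$element
    } else dy <- discovery
    return(sort(names(dy)[dy <= year]))
  }
  sp <- snapshot(space, year)
  sort(unique(sp$tokens$symbol))
}

#' Theoretical numbers of element combinations
#'
#' With `n` known elements, the number of possible combinations of size `s`
#' is the binomial coefficient `choose(n, s)`; the total number of possible
#' multi-element combinations is `2^n - n - 1` (all subsets minus the empty
#' set and the singletons). These are rough upper bounds that ignore valence
#' and compound stability. `theo_total_exact()` returns the exact decimal
#' string, needed because `2^60 - 61` exceeds exact double-precision range.
#'
#' @param n number of elements.
#' @param s combination size, `0 <= s <= n`.
#' @return a numeric count (`theo_total_exact`: a character scalar).
#' @examples
#' theo_total(11)          # 2036
#' theo_total_exact(60)    # "1152921504606846915"
#' @export
theo_combinations <- function(n, s) {
  if (s < 0 || s > n) .stopf("require 0 <= s <= n")
  round(choose(n, s))
}

#' @rdname theo_combinations
#' @export
theo_total <- function(n) {
  if (n < 2) .stopf("theoretical combination total requires n >= 2")
  2^n - n - 1
}

#' @rdname theo_combinations
#' @export
theo_total_exact <- function(n) {
  if (n < 2) .stopf("theoretical combination total requires n >= 2")
  d <- .big_from_int(1)
  for (i in seq_len(n)) d <- .big_double(d)
  .big_render(.big_sub_small(d, n + 1))
}

#' Fraction of theoretical combinations realized
#'
#' Compares what has been observed against what is combinatorially possible:
#' the number of distinct observed element combinations of size `s` in the
#' snapshot, divided by `choose(n, s)` for the `n` elements known that year.
#' The alternative reading -- counting substances whose combination has size
#' `s` rather than distinct combinations -- is available via `count`.
#'
#' @inheritParams elements_known
#' @param s combination size.
#' @param count `"combinations"` (default) or `"substances"`.
#' @return a fraction in `[0, 1]` (may exceed 1 for `count = "substances"`).
#' @export
realized_fraction <- function(space, year, s,
                              count = c("combinations", "substances"),
                              discovery = NULL) {
  count <- match.arg(count)
  sp <- snapshot(space, year)
  n <- length(elements_known(space, year, discovery))
  if (n < s) .stopf("only %d elements known by %d; cannot form size-%d combinations",
                    n, year, s)
  theo <- theo_combinations(n, s)
  if (theo == 0) .stopf("no theoretical combinations of size %d from %d elements", s, n)
  sub <- sp$substances[comb_size == s]
  num <- if (count == "combinations") length(unique(sub$combination)) else nrow(sub)
  num / theo
}

#' Combination coverage of the chemical space
#'
#' Answers "what percentage of the distinct combinations covers p% of the
#' substances?": combinations are sorted by substance count (descending, ties
#' broken lexicographically for determinism) and accumulated greedily until at
#' least `p`% of the snapshot's substances are covered.
#'
#' @inheritParams elements_known
#' @param p percentage of substances to cover, in `(0, 100]`.
#' @return the percentage of distinct combinations needed.
#' @export
combination_coverage <- function(space, year, p) {
  if (p <= 0 || p > 100) .stopf("p must be in (0, 100]")
  sp <- snapshot(space, year)
  if (nrow(sp$substances) == 0) .stopf("empty snapshot at %d", year)
  cnt <- sp$substances[, .N, by = combination]
  data.table::setorder(cnt, -N, combination)
  target <- p / 100 * nrow(sp$substances)
  k <- which(cumsum(cnt$N) >= target - 1e-9)[1]
  100 * k / nrow(cnt)
}

#' Span of an element or combination over the chemical space
#'
#' `element_span()` is the fraction of snapshot substances containing element
#' `element`; `combination_span()` the fraction having exactly combination
#' `combination`. Element spans are nonadditive: a single substance counts
#' toward each of its elements (H2O contributes to both H and O).
#'
#' @inheritParams elements_known
#' @param element an element symbol.
#' @param combination a combination string (lexicographic symbol
#'   concatenation, e.g. `"HO"`).
#' @return a fraction in `[0, 1]`.
#' @export
element_span <- function(space, year, element) {
  sp <- snapshot(space, year)
  if (nrow(sp$substances) == 0) .stopf("empty snapshot at %d", year)
  length(unique(sp$tokens[symbol == element]$id)) / nrow(sp$substances)
}

#' @rdname element_span
#' @export
combination_span <- function(space, year, combination) {
  sp <- snapshot(space, year)
  if (nrow(sp$substances) == 0) .stopf("empty snapshot at %d", year)
  comb <- combination
  sum(sp$substances$combination == comb) / nrow(sp$substances)
}

#' Per-year growth and diversity statistics
#'
#' One row per year of the window: new and cumulative substance and distinct
#' combination counts and the number of elements known (by occurrence, or by
#' a supplied discovery table).
#'
#' @inheritParams elements_known
#' @return a data.table with columns `year`, `n_new_substances`,
#'   `n_new_combinations`, `n_substances_cum`, `n_combinations_cum`,
#'   `n_elements_known`.
#' @export
year_stats <- function(space, discovery = NULL) {
  stopifnot(inherits(space, "chemical_space"))
  years <- seq(space$window[1], space$window[2])
  subs <- space$substances
  first_comb <- subs[, .(first = min(year)), by = combination]
  new_sub <- subs[, .N, by = year]
  new_comb <- first_comb[, .N, by = .(year = first)]
  dt <- data.table::data.table(year = years)
  dt <- merge(dt, new_sub, by = "year", all.x = TRUE)
  data.table::setnames(dt, "N", "n_new_substances")
  dt <- merge(dt, new_comb, by = "year", all.x = TRUE)
  data.table::setnames(dt, "N", "n_new_combinations")
  for (col in c("n_new_substances", "n_new_combinations"))
    data.table::set(dt, which(is.na(dt[[col]])), col, 0L)
  dt[, n_substances_cum := cumsum(n_new_substances)]
  dt[, n_combinations_cum := cumsum(n_new_combinations)]
  dt[, n_elements_known := vapply(
        year, function(y) length(elements_known(space, y, discovery)), integer(1))]
  dt[]
}

#' Read and write substance tables
#'
#' Substance tables are delimited text (comma or tab, autodetected on read)
#' with columns `id`, `formula`, `year`. An optional `filter` function
#' (taking and returning the raw data.frame) supports user-defined curation
#' of raw records before parsing; no particular curation policy is built in.
#'
#' @param path file path.
#' @param filter optional curation function applied to the raw table.
#' @param window optional study window passed to [chemical_space()].
#' @return `read_substances()` returns a `chemical_space`;
#'   `write_substances()` invisibly returns `path`.
#' @export
read_substances <- function(path, filter = NULL, window = NULL) {
  raw <- data.table::fread(path, colClasses = list(character = "id"))
  if (!is.null(filter)) raw <- filter(raw)
  chemical_space(raw, window = window)
}

#' @rdname read_substances
#' @param space a `chemical_space`.
#' @export
write_substances <- function(space, path) {
  stopifnot(inherits(space, "chemical_space"))
  data.table::fwrite(space$substances[, .(id, formula, year)], path)
  invisible(path)
}
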