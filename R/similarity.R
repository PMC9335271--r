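# Element substitutability similarity and per-year maximum-similarity
# networks (systems of chemical elements, SCEs).

# multiplicity table of arranged formulae per element, for one snapshot
.profile_counts <- function(sp) {
  sp$arranged[, .(mult = .N), by = .(element, arranged)]
}

#' Arranged-formula profile of an element
#'
#' The multiset FX of arranged formulae contributed by every snapshot
#' substance containing element `element`: one entry per substance, with
#' multiplicity accruing when distinct substances (e.g. isomers) yield the
#' same arranged formula. Its cardinality equals the number of substances
#' containing the element.
#'
#' @param space a `chemical_space`.
#' @param year snapshot year.
#' @param element element symbol; must occur in the snapshot.
#' @return an object of class `element_profile`: list with `element`,
#'   `entries` (data.table: arranged, mult) and `cardinality`.
#' @export
element_profile <- function(space, year, element) {
  sp <- snapshot(space, year)
  e <- element
  entries <- sp$arranged[element == e, .(mult = .N), by = arranged]
  if (nrow(entries) == 0)
    .stopf("element '%s' does not occur in the %d snapshot", e, year)
  structure(list(element = e, entries = entries[order(arranged)],
                 cardinality = sum(entries$mult)),
            class = "element_profile")
}

#' @export
print.element_profile <- function(x, ...) {
  cat(sprintf("<element_profile> F%s: %d arranged formulae, cardinality %d\n",
              x$element, nrow(x$entries), x$cardinality))
  invisible(x)
}

#' Similarity quotient
#'
#' The substitutability similarity value given its two counts: the number of
#' profile entries of the source element whose arranged formula also occurs
#' in the target element's profile support, divided by the source profile's
#' cardinality. Exposed separately because the counts themselves are
#' meaningful reported quantities; values are reported rounded to two
#' decimals.
#'
#' @param numerator shared-entry count (non-negative integer).
#' @param cardinality source profile cardinality (positive integer).
#' @return the exact ratio as a numeric scalar.
#' @examples
#' round(similarity_quotient(344, 659), 2)   # 0.52
#' round(similarity_quotient(349, 1556), 2)  # 0.22
#' @export
similarity_quotient <- function(numerator, cardinality) {
  if (cardinality <= 0) .stopf("profile cardinality must be positive")
  if (numerator < 0 || numerator > cardinality)
    .stopf("numerator must lie in [0, cardinality]")
  numerator / cardinality
}

#' Asymmetric element substitutability similarity
#'
#' `s(x -> y)`: the probability that a substance containing `x`, drawn
#' uniformly from the snapshot, has an arranged formula (with `x` as the
#' placeholder) that also occurs among the arranged formulae of `y` --
#' chemically, how often `x` could be substituted by `y` and still hit a
#' known compound. The numerator counts FX entries *with multiplicity*
#' against membership in FY's support, which makes the relation asymmetric:
#' `s(x -> y)` and `s(y -> x)` generally differ in both numerator and
#' denominator.
#'
#' @inheritParams element_profile
#' @param x,y distinct element symbols present in the snapshot.
#' @return an object of class `similarity_value`: list with `source`,
#'   `target`, `numerator`, `denominator`, `value`.
#' @export
similarity <- function(space, year, x, y) {
  if (identical(x, y)) .stopf("similarity is defined only between distinct elements")
  fx <- element_profile(space, year, x)
  fy <- element_profile(space, year, y)
  num <- sum(fx$entries[arranged %in% fy$entries$arranged]$mult)
  structure(list(source = x, target = y, numerator = num,
                 denominator = fx$cardinality,
                 value = similarity_quotient(num, fx$cardinality)),
            class = "similarity_value")
}

#' @export
print.similarity_value <- function(x, ...) {
  cat(sprintf("s(%s -> %s) = %d/%d = %.2f\n", x$source, x$target,
              x$numerator, x$denominator, x$value))
  invisible(x)
}

#' All pairwise similarities in one snapshot
#'
#' Computes every nonzero `s(source -> target)` in one pass over the
#' arranged-formula table. Pairs with no shared arranged formula are omitted
#' (their similarity is 0).
#'
#' @inheritParams element_profile
#' @return a data.table with columns `source`, `target`, `numerator`,
#'   `denominator`, `value`, sorted by source then descending value.
#' @export
similarity_matrix <- function(space, year) {
  sp <- snapshot(space, year)
  counts <- .profile_counts(sp)
  card <- counts[, .(denominator = sum(mult)), by = element]
  support <- counts[, .(target = element, arranged)]
  num <- merge(counts, support, by = "arranged",
               allow.cartesian = TRUE)[element != target,
               .(numerator = sum(mult)), by = .(source = element, target)]
  out <- merge(num, card, by.x = "source", by.y = "element")
  out[, value := numerator / denominator]
  data.table::setorder(out, source, -value, target)
  out[]
}

#' Most similar element(s)
#'
#' The argmax set of `s(x -> .)` over all other snapshot elements. Ties are
#' all retained; the set is empty when the maximum similarity is 0 (the
#' element shares no arranged formula with any other).
#'
#' @inheritParams element_profile
#' @param x element symbol.
#' @return a character vector (possibly empty), sorted.
#' @export
most_similar <- function(space, year, x) {
  sm <- similarity_matrix(space, year)
  mine <- sm[source == x & value > 0]
  if (nrow(mine) == 0) return(character(0))
  sort(mine[value == max(value)]$target)
}

#' Directed maximum-similarity network (system of chemical elements)
#'
#' For one snapshot, builds the directed graph whose nodes are the elements
#' occurring in at least one substance and whose edges point from each
#' element to its most similar element(s) (all ties retained; no edge when
#' the maximum similarity is 0). Node attributes: `n_substances` (substance
#' count) and, when a weight table is supplied, `aw_rank` (position in
#' ascending atomic-weight order among the snapshot's elements; elements
#' missing from the table get `NA` with a warning). Edge attributes carry the
#' similarity value and its exact numerator/denominator.
#'
#' @inheritParams element_profile
#' @param weights optional atomic weights: a [weight_table()] or a named
#'   numeric vector. Defaults to modern weights via [element_weights()].
#' @return an `igraph` directed graph with graph attribute `year`.
#' @export
sce_network <- function(space, year, weights = element_weights()) {
  sp <- snapshot(space, year)
  if (nrow(sp$substances) == 0) .stopf("empty snapshot at %d", year)
  nodes <- sp$tokens[, .(n_substances = data.table::uniqueN(id)), by = symbol]
  data.table::setnames(nodes, "symbol", "name")
  data.table::setorder(nodes, name)

  if (inherits(weights, "weight_table")) weights <- weights$weights
  if (!is.null(weights)) {
    w <- weights[nodes$name]
    if (anyNA(w))
      warning(sprintf("no atomic weight for element(s): %s; rank set to NA",
                      paste(nodes$name[is.na(w)], collapse = ", ")))
    nodes$aw_rank <- rank(w, ties.method = "first", na.last = "keep")
  } else nodes$aw_rank <- NA_integer_

  sm <- similarity_matrix(space, year)
  edges <- if (nrow(sm) > 0) {
    sm[sm[, .I[value == max(value) & value > 0], by = source]$V1]
  } else sm
  g <- igraph::graph_from_data_frame(
    edges[, .(from = source, to = target, weight = value,
              numerator, denominator)],
    directed = TRUE, vertices = nodes)
  g <- igraph::set_graph_attr(g, "year", as.integer(year))
  g
}

#' Edge set of a similarity network
#'
#' The directed most-similar pairs of an SCE as a character vector of
#' `"x->y"` labels with set semantics (sorted, unique). This is the
#' representation on which network overlap, backbone and retrodiction scores
#' operate.
#'
#' @param net an `igraph` network from [sce_network()], or an already-built
#'   character edge-label vector (returned unchanged after sorting).
#' @return sorted character vector of `"x->y"` labels.
#' @export
edge_set <- function(net) {
  if (is.character(net)) return(sort(unique(net)))
  stopifnot(inherits(net, "igraph"))
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(character(0))
  sort(unique(paste0(el[, 1], "->", el[, 2])))
}

#' Networks for a sequence of years
#'
#' @inheritParams sce_network
#' @param years integer vector of snapshot years.
#' @return a named list (year -> igraph) for years with nonempty snapshots.
#' @export
sce_series <- function(space, years, weights = element_weights()) {
  years <- as.integer(years)
  out <- list()
  for (y in years) {
    sp <- snapshot(space, y)
    if (nrow(sp$substances) == 0) next
    out[[as.character(y)]] <- sce_network(sp, y, weights)
  }
  out
}

#' Export a similarity network
#'
#' `write_sce_graphml()` writes GraphML; `write_sce_json()` writes a JSON
#' edge list (source, target, value, numerator, denominator) plus node
#' metadata.
#'
#' @param net an igraph network from [sce_network()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_sce_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_sce_graphml
#' @export
write_sce_json <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "both")
  names(el$edges)[names(el$edges) == "from"] <- "source"
  names(el$edges)[names(el$edges) == "to"] <- "target"
  names(el$edges)[names(el$edges) == "weight"] <- "value"
  jsonlite::write_json(
    list(year = igraph::graph_attr(net, "year"),
         nodes = el$vertices, edges = el$edges),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
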