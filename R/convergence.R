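# Convergence of yearly similarity networks: overlap between SCEs, the
# historical backbone, and similarity ubiquity under space subsampling.

#' Overlap from one SCE edge set toward another
#'
#' The fraction of the directed most-similar pairs of `nx` that are also
#' present in `ny`: `|Nx intersect Ny| / |Nx|`. Asymmetric; equals 1 exactly
#' when `nx` is contained in `ny`.
#'
#' @param nx,ny igraph networks or `"x->y"` edge-label vectors (see
#'   [edge_set()]). `nx` must be nonempty.
#' @return a fraction in `[0, 1]`.
#' @export
network_overlap <- function(nx, ny) {
  ex <- edge_set(nx); ey <- edge_set(ny)
  if (length(ex) == 0) .stopf("overlap undefined: source edge set is empty")
  length(intersect(ex, ey)) / length(ex)
}

#' Year-by-year SCE overlap matrix
#'
#' Entry `(row r, column c)` is the overlap from the SCE of column-year `c`
#' toward the SCE of row-year `r`: row `y` shows how similar every year's
#' SCE is to year `y`'s. The diagonal is 1 by construction.
#'
#' @param networks named list (year -> igraph) as from [sce_series()]; at
#'   least two years.
#' @return a numeric matrix with year dimnames.
#' @export
overlap_matrix <- function(networks) {
  if (length(networks) < 2) .stopf("need at least two yearly networks")
  yrs <- names(networks)
  sets <- lapply(networks, edge_set)
  m <- matrix(NA_real_, length(yrs), length(yrs), dimnames = list(yrs, yrs))
  for (c in seq_along(yrs)) {
    ec <- sets[[c]]
    for (r in seq_along(yrs)) {
      m[r, c] <- if (r == c) 1
                 else if (length(ec) == 0) NA_real_
                 else length(intersect(ec, sets[[r]])) / length(ec)
    }
  }
  m
}

#' Backbone of the yearly similarity networks
#'
#' A directed most-similar pair `i->j` belongs to the backbone when it
#' appears in more than `threshold` percent of the yearly SCEs in which it
#' could have appeared. Its ubiquity percentage is
#' `100 * f(i->j) / (end_year - y)`, where `f` counts the SCEs containing
#' the edge and `y` is the first year in which both `i` and `j` are SCE
#' nodes; the denominator is the width of the observation window. Edges
#' whose window is zero (both elements first appear in `end_year`) are
#' excluded with a message. With `report = "pairs"`, an unordered pair
#' qualifies when either direction passes the threshold, and all qualifying
#' directions are recorded.
#'
#' @param networks named list (year -> igraph), covering a contiguous year
#'   range ending at `end_year`.
#' @param threshold ubiquity percentage that must be strictly exceeded
#'   (default 60).
#' @param end_year last year of the window; defaults to the maximum network
#'   year.
#' @param report `"directed"` (default) or `"pairs"`.
#' @return a data.table with columns `i`, `j`, `first_year`, `frequency`,
#'   `ubiquity_percent` (and `pair` for `report = "pairs"`).
#' @export
backbone <- function(networks, threshold = 60, end_year = NULL,
                     report = c("directed", "pairs")) {
  report <- match.arg(report)
  yrs <- as.integer(names(networks))
  if (is.null(end_year)) end_year <- max(yrs)
  node_sets <- lapply(networks, function(g) igraph::V(g)$name)
  sets <- lapply(networks, edge_set)
  all_edges <- sort(unique(unlist(sets)))
  if (length(all_edges) == 0)
    return(data.table::data.table(i = character(0), j = character(0),
                                  first_year = integer(0), frequency = integer(0),
                                  ubiquity_percent = numeric(0)))
  parts <- data.table::tstrsplit(all_edges, "->", fixed = TRUE)
  dt <- data.table::data.table(edge = all_edges, i = parts[[1]], j = parts[[2]])
  dt[, first_year := vapply(seq_len(.N), function(k) {
    ok <- vapply(node_sets, function(ns) dt$i[k] %in% ns && dt$j[k] %in% ns,
                 logical(1))
    if (!any(ok)) NA_integer_ else min(yrs[ok])
  }, integer(1))]
  dt[, frequency := vapply(edge, function(e)
        sum(vapply(sets, function(s) e %in% s, logical(1))), numeric(1))]
  zero <- dt$first_year == end_year
  if (any(zero)) {
    message(sprintf("excluding %d edge(s) with zero-width observation window (first year = end year)",
                    sum(zero)))
    dt <- dt[!zero]
  }
  dt[, ubiquity_percent := 100 * frequency / (end_year - first_year)]
  if (report == "directed") {
    out <- dt[ubiquity_percent > threshold]
  } else {
    dt[, pair := paste(pmin(i, j), pmax(i, j), sep = "--")]
    ok_pairs <- unique(dt[ubiquity_percent > threshold]$pair)
    out <- dt[pair %in% ok_pairs]
  }
  out[, edge := NULL]
  data.table::setorder(out, -ubiquity_percent, i, j)
  out[]
}

# most-similar directed edges from an arranged-formula table subset
.max_edges <- function(at) {
  if (nrow(at) == 0) return(character(0))
  counts <- at[, .(mult = .N), by = .(element, arranged)]
  card <- counts[, .(den = sum(mult)), by = element]
  support <- counts[, .(target = element, arranged)]
  num <- merge(counts, support, by = "arranged",
               allow.cartesian = TRUE)[element != target,
               .(numerator = sum(mult)), by = .(source = element, target)]
  if (nrow(num) == 0) return(character(0))
  num <- merge(num, card, by.x = "source", by.y = "element")
  num[, value := numerator / den]
  mx <- num[num[, .I[value == max(value) & value > 0], by = source]$V1]
  paste0(mx$source, "->", mx$target)
}

#' Ubiquity of most-similar relations under subsampling
#'
#' How small a random fraction of the chemical space suffices to still
#' detect each most-similar relation of the full snapshot. For every sample
#' size `s` percent, `reps` uniform substance subsamples are drawn without
#' replacement, the most-similar relations are rebuilt on each subsample,
#' and the appearances of every full-space edge are counted. Elements absent
#' from a subsample simply drop out of that replicate's network. Each
#' `(sample size, replicate)` pair uses its own RNG stream derived from the
#' master seed, so adding sample sizes leaves existing replicates unchanged.
#'
#' @inheritParams element_profile
#' @param sample_sizes percentages of the space to sample (default 5..95 by
#'   5, the 19-size grid).
#' @param reps replicates per size (default 100).
#' @param seed master seed (mandatory: subsampling is stochastic).
#' @return a data.table with columns `edge`, `sample_size`, `count`, `reps`,
#'   `seed`; one row per full-space edge and sample size.
#' @export
ubiquity <- function(space, year, sample_sizes = seq(5, 95, by = 5),
                     reps = 100, seed) {
  if (missing(seed)) .stopf("a seed is required for subsampling")
  sp <- snapshot(space, year)
  n <- nrow(sp$substances)
  if (n == 0) .stopf("empty snapshot at %d", year)
  full_edges <- edge_set(sce_network(sp, year, weights = NULL))
  at <- sp$arranged
  ids <- sp$substances$id
  out <- list()
  for (s in sample_sizes) {
    k <- round(s / 100 * n)
    if (k < 1) { warning(sprintf("sample size %s%% yields 0 substances; skipped", s)); next }
    counts <- stats::setNames(integer(length(full_edges)), full_edges)
    for (r in seq_len(reps)) {
      set.seed(.substream(seed, s, r))
      take <- sample(ids, k)
      got <- .max_edges(at[id %in% take])
      hit <- full_edges[full_edges %in% got]
      counts[hit] <- counts[hit] + 1L
    }
    out[[as.character(s)]] <- data.table::data.table(
      edge = full_edges, sample_size = s, count = as.integer(counts),
      reps = reps, seed = seed)
  }
  data.table::rbindlist(out)
}
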