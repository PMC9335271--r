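# Retrodiction: rebuild chemical spaces as seen through historical
# atomic-weight systems by rescaling modern formulae with simple fractions
# (Farey approximation), then score the resulting SCEs against a reference.

#' A chemist's atomic-weight table
#'
#' Holds a historical (or synthetic) system of atomic weights `A(e)` on the
#' chemist's own scale, together with the reference element the scale is
#' expressed against (hydrogen unless stated otherwise). All weight ratios
#' used in rescaling are taken relative to this reference.
#'
#' @param chemist name of the chemist or system.
#' @param year publication year of the table.
#' @param weights named numeric vector, element symbol -> atomic weight; all
#'   positive, reference element present.
#' @param reference reference element symbol (default `"H"`).
#' @return an object of class `weight_table`.
#' @export
weight_table <- function(chemist, year, weights, reference = "H") {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    .stopf("weights must be a named vector")
  if (any(weights <= 0)) .stopf("atomic weights must be positive")
  if (!reference %in% names(weights))
    .stopf("reference element '%s' missing from the table", reference)
  structure(list(chemist = chemist, year = as.integer(year),
                 weights = weights, reference = reference),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %s (%d): %d elements, reference %s\n",
              x$chemist, x$year, length(x$weights), x$reference))
  invisible(x)
}

#' Read/write weight tables as delimited text
#'
#' Columns: `chemist`, `year`, `element`, `weight`, `reference_element`.
#' A file may hold several chemists' tables; `read_weight_tables()` returns
#' a named list of [weight_table()] objects.
#'
#' @param path file path.
#' @return a named list of `weight_table` objects.
#' @export
read_weight_tables <- function(path) {
  raw <- data.table::fread(path)
  need <- c("chemist", "year", "element", "weight", "reference_element")
  if (!all(need %in% names(raw)))
    .stopf("weight table file must have columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(raw, raw$chemist), function(d) {
    w <- d$weight; names(w) <- d$element
    weight_table(d$chemist[1], d$year[1], w, d$reference_element[1])
  })
  out
}

#' @rdname read_weight_tables
#' @param table a `weight_table`.
#' @export
write_weight_table <- function(table, path) {
  stopifnot(inherits(table, "weight_table"))
  data.table::fwrite(data.table::data.table(
    chemist = table$chemist, year = table$year,
    element = names(table$weights), weight = unname(table$weights),
    reference_element = table$reference), path, sep = "\t")
  invisible(path)
}

#' Simplest Farey fraction within a relative-error tolerance
#'
#' Finds the fraction `p/q` in `(0, 1]` approximating `r` with relative
#' error `|r - p/q| / r <= tau`. The default method returns the fraction
#' with the smallest denominator satisfying the bound (ties at equal
#' denominator broken by minimal error), i.e. the earliest qualifying member
#' encountered when sweeping Farey sequences of increasing order; the search
#' always terminates because the approximation error of the best order-`n`
#' fraction vanishes as `n` grows. `method = "min_error"` instead returns
#' the global minimum-error fraction among denominators up to `max_order`
#' (still required to satisfy the bound).
#'
#' @param r target ratio in `(0, 1]`.
#' @param tau relative-error tolerance in `(0, 0.2]`.
#' @param method `"smallest_denominator"` (default) or `"min_error"`.
#' @param max_order denominator cap for `method = "min_error"`.
#' @return a list with `p`, `q` (reduced), `value` and `error` (achieved
#'   relative error).
#' @examples
#' farey_best(0.4375, 0.01)  # 7/16
#' farey_best(0.30, 0.15)    # 1/3
#' @export
farey_best <- function(r, tau, method = c("smallest_denominator", "min_error"),
                       max_order = 1000) {
  method <- match.arg(method)
  if (r <= 0 || r > 1) .stopf("r must be in (0, 1]")
  if (tau <= 0) .stopf("tau must be positive")
  cand <- function(q) {
    p <- unique(pmin(q, pmax(1, c(floor(r * q), floor(r * q) + 1))))
    err <- abs(r - p / q) / r
    i <- which.min(err)
    g <- .gcd(p[i], q)
    list(p = p[i] / g, q = q / g, value = p[i] / q, error = err[i])
  }
  if (method == "smallest_denominator") {
    q <- 1
    repeat {
      b <- cand(q)
      if (b$error <= tau) return(b)
      q <- q + 1
      if (q > 1e7) .stopf("farey search failed to terminate")  # unreachable guard
    }
  }
  best <- NULL
  for (q in seq_len(max_order)) {
    b <- cand(q)
    if (is.null(best) || b$error < best$error) best <- b
  }
  if (best$error > tau)
    .stopf("no fraction with denominator <= %d achieves tolerance %g", max_order, tau)
  g <- .gcd(best$p, best$q)
  list(p = best$p / g, q = best$q / g, value = best$value, error = best$error)
}

#' Formula-rescaling coefficient for one element
#'
#' Computes the multiplier `f_A(e)` applied to element `e`'s stoichiometric
#' coefficients when a modern formula is reinterpreted under chemist `A`'s
#' atomic weights. Both hydrogen-relative ratios are computed:
#' `wa = (W(e)/W(H)) / (A(e)/A(H))` and its reciprocal `aw`. The multiplier
#' approximates `wa`: when `wa <= 1` it is the simplest Farey fraction
#' within `tau`; when `wa = alpha + beta` with integer `alpha >= 1`, it is
#' `alpha` plus the Farey approximation of `beta`. Multiplying modern
#' coefficients by `wa` preserves the substance's elemental mass ratios when
#' read with the chemist's weights; this direction reproduces the classic
#' Fe2O3 -> FeO3 correspondence under an iron-doubled weight system.
#'
#' @param element element symbol, present in both weight systems.
#' @param A a [weight_table()].
#' @param tau relative-error tolerance (the achieved error of the fractional
#'   part never exceeds it).
#' @param W modern weights (named numeric; default [element_weights()]).
#' @param method passed to [farey_best()].
#' @return an object of class `rescale_coefficient`: list with `element`,
#'   `num`, `den` (reduced multiplier), `value`, `tau`, `error` (achieved
#'   relative error of the multiplier against `wa`), `wa`, `aw`.
#' @export
rescale_coefficient <- function(element, A, tau, W = element_weights(),
                                method = "smallest_denominator") {
  stopifnot(inherits(A, "weight_table"))
  e <- element
  if (!e %in% names(A$weights))
    .stopf("element '%s' is untranslatable: absent from %s's weight table",
           e, A$chemist)
  if (!e %in% names(W)) .stopf("element '%s' has no modern weight", e)
  ref <- A$reference
  if (!ref %in% names(W))
    .stopf("reference element '%s' has no modern weight", ref)
  wa <- (W[[e]] / W[[ref]]) / (A$weights[[e]] / A$weights[[ref]])
  aw <- 1 / wa
  if (wa <= 1) {
    fb <- farey_best(wa, tau, method = method)
    num <- fb$p; den <- fb$q
  } else {
    alpha <- floor(wa)
    beta <- wa - alpha
    if (beta == 0) { num <- alpha; den <- 1 }
    else {
      fb <- farey_best(beta, tau, method = method)
      rr <- .rat(alpha * fb$q + fb$p, fb$q)
      num <- rr$num; den <- rr$den
    }
  }
  value <- num / den
  structure(list(element = e, num = num, den = den, value = value,
                 tau = tau, error = abs(wa - value) / wa, wa = wa, aw = aw),
            class = "rescale_coefficient")
}

#' @export
print.rescale_coefficient <- function(x, ...) {
  cat(sprintf("f(%s) = %s (wa = %.4f, achieved error %.4f, tau %.2f)\n",
              x$element, .rat_render(x$num, x$den), x$wa, x$error, x$tau))
  invisible(x)
}

#' Rescale a formula to a historical atomic-weight system
#'
#' Multiplies every coefficient of `f` by its element's rescaling
#' multiplier, then normalizes the exact rational result to the smallest
#' positive-integer coefficient vector (multiply through by the LCM of
#' denominators, divide by the GCD of numerators). The normalization makes
#' the result scale-invariant: `F` and `2F` rescale to the same formula.
#'
#' @param f a `chem_formula` or formula string.
#' @param A a [weight_table()]; every element of `f` must be present.
#' @inheritParams rescale_coefficient
#' @return a `chem_formula`.
#' @examples
#' berz <- perturb_weights(elements = "Fe", factors = 2,
#'                         chemist = "iron-doubled", year = 1819)
#' render_formula(rescale_formula("Fe2O3", berz, tau = 0.05))  # "FeO3"
#' @export
rescale_formula <- function(f, A, tau, W = element_weights(),
                            method = "smallest_denominator") {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  k <- length(f$symbol)
  num <- den <- numeric(k)
  identity_scaling <- TRUE
  for (i in seq_len(k)) {
    rc <- rescale_coefficient(f$symbol[i], A, tau, W, method)
    if (rc$num != 1 || rc$den != 1) identity_scaling <- FALSE
    nc <- .rat_mul(.rat(f$num[i], f$den[i]), .rat(rc$num, rc$den))
    num[i] <- nc$num; den[i] <- nc$den
  }
  # when every multiplier is exactly 1 the formula is already expressed in
  # the chemist's system: return it untouched (no GCD reduction, so isomer
  # and polymer records keep their empirical coefficients)
  if (identity_scaling) return(f)
  L <- Reduce(.lcm, den)
  num <- num * (L / den)
  g <- Reduce(.gcd, num)
  structure(list(symbol = f$symbol, num = num / g, den = rep(1, k)),
            class = "chem_formula")
}

#' Chemical space as seen through a chemist's atomic weights
#'
#' Takes the snapshot at `year` (by default the year before the table's
#' publication, inclusive) and rescales every substance formula to the
#' chemist's weight system at tolerance `tau`. Substances containing
#' elements absent from the table are dropped (the chemist's system is
#' restricted to his elements); the number dropped is recorded in attribute
#' `n_dropped` and messaged.
#'
#' @param space a `chemical_space`.
#' @param A a [weight_table()].
#' @param tau relative-error tolerance.
#' @param year snapshot year; default `A$year - 1`.
#' @inheritParams rescale_coefficient
#' @return a `chemical_space` of rescaled substances (attribute `n_dropped`).
#' @export
retro_space <- function(space, A, tau, year = A$year - 1,
                        W = element_weights(), method = "smallest_denominator") {
  stopifnot(inherits(space, "chemical_space"), inherits(A, "weight_table"))
  sp <- snapshot(space, year)
  known <- names(A$weights)
  bad_ids <- unique(sp$tokens[!symbol %in% known]$id)
  keep <- sp$substances[!id %in% bad_ids]
  if (nrow(keep) == 0)
    .stopf("no substance of the %d snapshot is expressible in %s's system",
           year, A$chemist)
  if (length(bad_ids) > 0)
    message(sprintf("dropped %d substance(s) with elements outside %s's system",
                    length(bad_ids), A$chemist))
  uf <- unique(keep$formula)
  resc <- vapply(uf, function(s)
    render_formula(rescale_formula(s, A, tau, W, method)), character(1))
  out <- chemical_space(
    data.frame(id = keep$id, formula = unname(resc[keep$formula]),
               year = keep$year),
    window = c(space$window[1], year))
  attr(out, "n_dropped") <- length(bad_ids)
  out
}

#' Score a retrodicted SCE against a reference year
#'
#' Builds three directed edge sets: `P` from the unrescaled snapshot at
#' `year - 1`, `P_tau` from the rescaled (retrodicted) space, and `P_ref`
#' from the reference-year snapshot. The true-positive rate is
#' `|P_tau intersect P_ref| / |P intersect P_ref|` -- how much of what modern
#' formulae would reveal of the reference SCE the chemist's weights also
#' reveal. The false-positive rate is `|P_tau \ P_ref| / |P_tau|` -- the
#' fraction of transient similarities not observed in the reference year.
#' An empty `P intersect P_ref` leaves the true-positive rate undefined
#' (`NA` with a warning).
#'
#' @inheritParams retro_space
#' @param reference_year year of the reference SCE (default: the space's
#'   last window year).
#' @return a one-row data.table: `chemist`, `tau`, `tp_rate`, `fp_rate`,
#'   `n_edges` (size of `P_tau`).
#' @export
retro_scores <- function(space, A, tau, reference_year = space$window[2],
                         W = element_weights(), method = "smallest_denominator") {
  y <- A$year - 1L
  p_ref <- edge_set(sce_network(space, reference_year, weights = NULL))
  p <- edge_set(sce_network(space, y, weights = NULL))
  rs <- retro_space(space, A, tau, year = y, W = W, method = method)
  p_tau <- edge_set(sce_network(rs, y, weights = NULL))
  den_tp <- length(intersect(p, p_ref))
  tp <- if (den_tp == 0) {
    warning(sprintf("true-positive rate undefined for %s at tau=%g: no overlap between the unperturbed SCE and the reference",
                    A$chemist, tau))
    NA_real_
  } else length(intersect(p_tau, p_ref)) / den_tp
  fp <- if (length(p_tau) == 0) NA_real_ else
    length(setdiff(p_tau, p_ref)) / length(p_tau)
  data.table::data.table(chemist = A$chemist, tau = tau, tp_rate = tp,
                         fp_rate = fp, n_edges = length(p_tau))
}

#' @rdname retro_scores
#' @param taus tolerance sweep; default the 20 levels 1%..20%.
#' @export
retro_score_sweep <- function(space, A, taus = seq(0.01, 0.20, by = 0.01),
                              reference_year = space$window[2],
                              W = element_weights(),
                              method = "smallest_denominator") {
  data.table::rbindlist(lapply(taus, function(t)
    retro_scores(space, A, t, reference_year, W, method)))
}

#' Agreement between the element orderings of two weight systems
#'
#' The fraction of unordered pairs of shared elements that both weight
#' tables rank in the same order (pairwise concordance). Ties count as
#' discordant unless tied in both systems.
#'
#' @param A,B [weight_table()] objects (or named numeric weight vectors)
#'   sharing at least two elements.
#' @return a fraction in `[0, 1]`.
#' @export
ordering_agreement <- function(A, B) {
  wa <- if (inherits(A, "weight_table")) A$weights else A
  wb <- if (inherits(B, "weight_table")) B$weights else B
  shared <- intersect(names(wa), names(wb))
  if (length(shared) < 2) .stopf("fewer than two shared elements")
  pairs <- utils::combn(shared, 2)
  da <- sign(wa[pairs[1, ]] - wa[pairs[2, ]])
  db <- sign(wb[pairs[1, ]] - wb[pairs[2, ]])
  mean((da == db & da != 0) | (da == 0 & db == 0))
}
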