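# Synthetic chemical-space generator with planted element families. Emulates
# the qualitative regimes of the historical record -- exponential growth of
# new substances, staged element introduction, reuse of element combinations,
# isomers, bounded combination sizes -- with known ground truth, so that every
# analysis stage can be validated without proprietary data.

#' Default element roster for the synthetic generator
#'
#' Sixty elements with stylized introduction years (9 available by 1800,
#' all 60 by 1868) and a chemically motivated family partition (alkali
#' metals, halogens, chalcogens, pnictogens, platinum metals, ...). Elements
#' of one family substitute for each other in generated substances; the
#' partition is the generator's planted ground truth.
#'
#' @return a data.frame with columns `element`, `intro_year`, `family`.
#' @export
default_roster <- function() {
  rbind(
    data.frame(element = c("H","C","N","O","P","S","Cl","Fe","Cu"),
               intro_year = 1800L),
    data.frame(element = c("Au","Ag","Hg","Nb"), intro_year = 1801L),
    data.frame(element = c("Pb","Sn","Zn","Ta"), intro_year = 1802L),
    data.frame(element = c("Pt","Ni","Co","Pd","Rh","Ce","Ir","Os"),
               intro_year = 1803L),
    data.frame(element = c("Sb","As","Bi","Mn"), intro_year = 1804L),
    data.frame(element = c("Mo","W","Te","Cr"), intro_year = 1805L),
    data.frame(element = c("Zr","Ti","U"), intro_year = 1806L),
    data.frame(element = c("Na","K"), intro_year = 1807L),
    data.frame(element = c("Ca","Sr","Ba","Mg","B"), intro_year = 1808L),
    data.frame(element = "I", intro_year = 1811L),
    data.frame(element = c("Li","Cd","Se"), intro_year = 1817L),
    data.frame(element = "Si", intro_year = 1823L),
    data.frame(element = "Al", intro_year = 1825L),
    data.frame(element = "Br", intro_year = 1826L),
    data.frame(element = c("Be","Th"), intro_year = 1828L),
    data.frame(element = "V", intro_year = 1830L),
    data.frame(element = "La", intro_year = 1839L),
    data.frame(element = "F", intro_year = 1840L),
    data.frame(element = "Ru", intro_year = 1844L),
    data.frame(element = "Cs", intro_year = 1860L),
    data.frame(element = c("Rb","Tl"), intro_year = 1861L),
    data.frame(element = "In", intro_year = 1863L)
  ) -> r
  fam <- list(
    organogens = c("H","C"),
    alkali = c("Li","Na","K","Rb","Cs"),
    alkaline_earth = c("Be","Mg","Ca","Sr","Ba"),
    boron_group = c("B","Al","In","Tl"),
    carbon_group = c("Si","Sn","Pb","Ti","Zr"),
    pnictogens = c("N","P","As","Sb","Bi"),
    chalcogens = c("O","S","Se","Te"),
    halogens = c("F","Cl","Br","I"),
    iron_triad = c("Fe","Co","Ni"),
    chromium_group = c("Cr","Mo","W","U"),
    vanadium_group = c("V","Mn","Nb","Ta"),
    platinum_metals = c("Ru","Rh","Pd","Os","Ir","Pt"),
    coinage = c("Cu","Ag","Au"),
    zinc_group = c("Zn","Cd","Hg"),
    rare_earths = c("La","Ce","Th"))
  map <- stats::setNames(rep(names(fam), lengths(fam)), unlist(fam))
  r$family <- unname(map[r$element])
  r[order(r$intro_year, r$element), ]
}

#' Generator configuration
#'
#' Bundles and validates the knobs of the synthetic chemical-space
#' generator. Defaults emulate the historical regime: window 1800-1868; the
#' staged 60-element roster of [default_roster()]; exponential growth of new
#' substances (20 expected in 1800, base 1.05 per year, roughly 11,000
#' cumulative substances by 1868); combination sizes 1-8 concentrated on 2-3;
#' template reuse rising from 0.35 to 0.65 after 1830 (decreasing
#' combination diversity); an organic bias that from 1830 on favors C, H, O
#' and N in newly created skeletons; and an isomer rate of 0.08.
#'
#' @param years window `c(first, last)`.
#' @param roster data.frame with columns `element`, `intro_year`, `family`;
#'   every family must have at least two members (substitution within a
#'   singleton family is infeasible).
#' @param base_count expected number of new substances in the first year.
#' @param growth exponential base (> 1) of the yearly expected count.
#' @param size_probs probabilities of combination sizes `1..8`.
#' @param reuse_prob length-2 vector: template-reuse probability before and
#'   after `reuse_change_year`.
#' @param reuse_change_year year at which the reuse probability switches.
#' @param isomer_rate probability a new substance duplicates an existing
#'   formula.
#' @param organic_bias_year year after which `organic_elements` are favored
#'   in new skeletons (weight `organic_weight` vs 1).
#' @param organic_elements,organic_weight see above.
#' @param max_coef largest stoichiometric coefficient drawn for any slot.
#' @param distinct_profiles when TRUE (default), new templates are rejected
#'   whenever any arranged formula they would create already belongs to a
#'   different element or template, so that arranged formulae are shared
#'   *only* through within-family slot substitution. This is the construction
#'   guarantee that substitutability, not abundance or coincidence, drives
#'   the planted similarities; set FALSE to allow coincidental cross-family
#'   resemblances as a stressor.
#' @param seed master seed (generation is fully deterministic given it).
#' @return a validated list of class `space_config`.
#' @export
space_config <- function(years = c(1800L, 1868L),
                         roster = default_roster(),
                         base_count = 20, growth = 1.05,
                         size_probs = c(0.05, 0.35, 0.30, 0.15, 0.08, 0.04, 0.02, 0.01),
                         reuse_prob = c(0.35, 0.65),
                         reuse_change_year = 1830L,
                         isomer_rate = 0.08,
                         organic_bias_year = 1830L,
                         organic_elements = c("C", "H", "O", "N"),
                         organic_weight = 5,
                         max_coef = 4L,
                         distinct_profiles = TRUE,
                         seed = 1L) {
  stopifnot(length(years) == 2, years[1] <= years[2])
  need <- c("element", "intro_year", "family")
  if (!all(need %in% names(roster)))
    .stopf("roster needs columns element, intro_year, family")
  if (!all(is_element_symbol(roster$element)))
    .stopf("roster contains unknown element symbols")
  fam_sizes <- table(roster$family)
  if (any(fam_sizes < 2))
    .stopf("infeasible config: family '%s' has a single member and cannot produce substitutions",
           names(fam_sizes)[fam_sizes < 2][1])
  if (growth <= 1) .stopf("growth base must exceed 1 for an exponential regime")
  if (length(size_probs) != 8 || any(size_probs < 0))
    .stopf("size_probs must give 8 non-negative probabilities (sizes 1..8)")
  if (isomer_rate < 0 || isomer_rate > 1) .stopf("isomer_rate must be in [0, 1]")
  structure(list(years = as.integer(years), roster = roster,
                 base_count = base_count, growth = growth,
                 size_probs = size_probs / sum(size_probs),
                 reuse_prob = reuse_prob,
                 reuse_change_year = as.integer(reuse_change_year),
                 isomer_rate = isomer_rate,
                 organic_bias_year = as.integer(organic_bias_year),
                 organic_elements = organic_elements,
                 organic_weight = organic_weight,
                 max_coef = as.integer(max_coef),
                 distinct_profiles = isTRUE(distinct_profiles),
                 seed = as.integer(seed)),
            class = "space_config")
}

.render_comp <- function(sym, coef) {
  o <- order(sym)
  paste0(sym[o], ifelse(coef[o] == 1, "", coef[o]), collapse = "")
}

#' Generate a synthetic chemical space with planted families
#'
#' Substances are built from family-indexed formula templates: a template is
#' a skeleton composition over elements outside the slot family plus a slot
#' coefficient, and every currently available member of the slot family is
#' instantiated into it ("full template sharing"). Members of the same family
#' therefore contribute identical arranged formulae, so substitutability --
#' not abundance -- drives the planted within-family similarity. Reuse events
#' re-emit an existing template's element combination with fresh
#' coefficients; isomer events duplicate an existing formula under a new id.
#' Each year draws from its own RNG substream of the master seed, so changing
#' one year's volume does not reshuffle the others.
#'
#' @param config a [space_config()].
#' @return a list with `space` (a [chemical_space()]), `truth` (data.table of
#'   planted directed pairs: `source`, `target`, `family`) and `yearly`
#'   (data.table: year, expected, emitted).
#' @export
generate_space <- function(config) {
  stopifnot(inherits(config, "space_config"))
  ro <- config$roster
  y0 <- config$years[1]; y1 <- config$years[2]
  templates <- list()        # each: list(slot_family, skel_sym, tid)
  formulas_seen <- new.env(hash = TRUE, parent = emptyenv())
  # arranged string -> owner label ("slot:<template id>" or "skel:<element>");
  # enforces that arranged formulae are shared only via within-family slots
  arr_owner <- new.env(hash = TRUE, parent = emptyenv())
  subs <- vector("list", 4096); nsub <- 0L
  slot_used <- new.env(hash = TRUE, parent = emptyenv())  # family -> members used as slots
  yearly <- list()

  # the arranged formulae one template variant would create, with owners
  variant_strings <- function(tid, skel_sym, skel_coef, slot_coef, members) {
    out <- list(list(
      s = .render_comp(c(skel_sym, "X"), c(skel_coef, slot_coef)),
      owner = paste0("slot:", tid)))
    for (m in members) for (i in seq_along(skel_sym)) {
      sym <- c(skel_sym, m); coef <- c(skel_coef, slot_coef)
      sym[i] <- "X"
      out[[length(out) + 1L]] <- list(s = .render_comp(sym, coef),
                                      owner = paste0("skel:", skel_sym[i]))
    }
    out
  }

  variant_ok <- function(strs) {
    if (!config$distinct_profiles) return(TRUE)
    claimed <- character(0)
    for (x in strs) {
      prev <- get0(x$s, envir = arr_owner, ifnotfound = NA_character_)
      if (is.na(prev) && x$s %in% names(claimed)) prev <- unname(claimed[x$s])
      if (!is.na(prev) && !identical(prev, x$owner)) return(FALSE)
      claimed[x$s] <- x$owner
    }
    TRUE
  }

  record_strings <- function(strs) {
    for (x in strs) assign(x$s, x$owner, envir = arr_owner)
  }

  add_sub <- function(formula, year) {
    nsub <<- nsub + 1L
    if (nsub > length(subs)) length(subs) <<- 2L * nsub
    subs[[nsub]] <<- list(id = sprintf("S%06d", nsub), formula = formula,
                          year = year)
    assign(formula, TRUE, envir = formulas_seen)
  }

  for (y in y0:y1) {
    set.seed(.substream(config$seed, y))
    lambda <- config$base_count * config$growth^(y - y0)
    n_y <- stats::rpois(1, lambda)
    avail <- ro$element[ro$intro_year <= y]
    fam_members <- split(ro$element[ro$element %in% avail],
                         ro$family[ro$element %in% avail])
    fam_ok <- names(fam_members)[lengths(fam_members) >= 2]
    if (length(fam_ok) == 0) .stopf("no feasible family available in %d", y)
    reuse_p <- if (y < config$reuse_change_year) config$reuse_prob[1] else config$reuse_prob[2]
    skel_w <- stats::setNames(rep(1, length(avail)), avail)
    if (y >= config$organic_bias_year)
      skel_w[names(skel_w) %in% config$organic_elements] <- config$organic_weight

    emitted <- 0L
    guard <- 0L
    while (emitted < n_y && guard < 50L * (n_y + 1L)) {
      guard <- guard + 1L
      if (nsub > 0L && stats::runif(1) < config$isomer_rate) {
        pick <- subs[[sample.int(nsub, 1)]]
        add_sub(pick$formula, y)
        emitted <- emitted + 1L
        next
      }
      new_template <- FALSE
      if (length(templates) > 0L && stats::runif(1) < reuse_p) {
        tp <- templates[[sample.int(length(templates), 1)]]
        if (!all(tp$skel_sym %in% avail) ||
            length(fam_members[[tp$slot_family]] %||% character(0)) < 2) next
        skel_sym <- tp$skel_sym
        slot_family <- tp$slot_family
        tid <- tp$tid
      } else {
        slot_family <- sample(fam_ok, 1)
        s <- sample.int(8L, 1, prob = config$size_probs)
        pool <- setdiff(avail, fam_members[[slot_family]])
        if (length(pool) < s - 1L) next
        skel_sym <- if (s == 1L) character(0) else
          sample(pool, s - 1L, prob = skel_w[pool])
        tid <- length(templates) + 1L
        new_template <- TRUE
      }
      skel_coef <- if (length(skel_sym)) sample.int(config$max_coef, length(skel_sym),
                                                    replace = TRUE) else integer(0)
      slot_coef <- sample.int(config$max_coef, 1)
      members <- fam_members[[slot_family]]
      fs <- vapply(members, function(m)
        .render_comp(c(skel_sym, m), c(skel_coef, slot_coef)), character(1))
      if (any(vapply(fs, function(f) exists(f, envir = formulas_seen),
                     logical(1)))) next  # coefficient variant already realized
      strs <- variant_strings(tid, skel_sym, skel_coef, slot_coef, members)
      if (!variant_ok(strs)) next       # would leak an arranged formula across owners
      record_strings(strs)
      if (new_template)
        templates[[tid]] <- list(slot_family = slot_family,
                                 skel_sym = skel_sym, tid = tid)
      for (i in seq_along(members)) add_sub(fs[i], y)
      used <- get0(slot_family, envir = slot_used, ifnotfound = character(0))
      assign(slot_family, union(used, members), envir = slot_used)
      emitted <- emitted + length(members)
    }
    yearly[[as.character(y)]] <- data.table::data.table(
      year = y, expected = lambda, emitted = emitted)
  }

  dt <- data.table::rbindlist(subs[seq_len(nsub)])
  space <- chemical_space(dt, window = config$years)

  truth <- data.table::rbindlist(lapply(ls(slot_used), function(fm) {
    mem <- sort(get(fm, envir = slot_used))
    if (length(mem) < 2) return(NULL)
    eg <- expand.grid(source = mem, target = mem, stringsAsFactors = FALSE)
    eg <- eg[eg$source != eg$target, ]
    data.table::data.table(source = eg$source, target = eg$target, family = fm)
  }))
  list(space = space, truth = truth,
       yearly = data.table::rbindlist(yearly))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hand-auditable 13-substance toy space
#'
#' A fixed toy chemical space of 13 substances over seven elements (H, C, O,
#' Na, K, Cl, Br and their compounds), small enough that every arranged
#' formula, every profile and every similarity value can be verified by hand.
#' The expected similarity values, worked out manually, ship as the package
#' fixture `toy_expected_similarities.csv` (see
#' `system.file("extdata", package = "chemspacer")`). Highlights at the final
#' year: s(Br->Cl) = 4/5 (isomers make C2H2X2 count twice in FBr),
#' s(Cl->Br) = 3/5, K is tied between H and Na, and O and C share no
#' arranged formula with anyone.
#'
#' @return a `chemical_space` of 13 substances, window 1800-1868.
#' @export
toy_space <- function() {
  chemical_space(data.frame(
    id = sprintf("W%02d", 1:13),
    formula = c("H2O", "HCl", "NaCl", "K2O", "Na2O", "KCl", "HBr",
                "NaBr", "C2H2Cl2", "C2H2Br2", "C2H2Br2", "CBr4", "CHCl3"),
    year = c(1800, 1800, 1807, 1807, 1807, 1808, 1826,
             1826, 1835, 1840, 1845, 1850, 1842)),
    window = c(1800L, 1868L))
}

#' Perturbed weight table for retrodiction experiments
#'
#' Builds a synthetic historical-style atomic-weight table by multiplying
#' selected modern hydrogen-relative weights by exact rational factors, so
#' the rescaling multipliers the retrodiction module should recover are
#' known in closed form (the reciprocal of each factor).
#'
#' @param W modern weights (named numeric; default [element_weights()]).
#' @param elements elements to perturb.
#' @param factors positive factors, recycled along `elements`.
#' @param chemist,year metadata for the resulting table.
#' @param keep optional character vector: restrict the table to these
#'   elements (plus the reference); default keeps all of `W`.
#' @return a [weight_table()].
#' @export
perturb_weights <- function(W = element_weights(), elements = character(0),
                            factors = numeric(0), chemist = "synthetic",
                            year = 1850L, keep = NULL) {
  if (length(elements)) {
    factors <- rep_len(factors, length(elements))
    if (any(factors <= 0)) .stopf("perturbation factors must be positive")
    W[elements] <- W[elements] * factors
  }
  if (!is.null(keep)) W <- W[union("H", keep)]
  weight_table(chemist, year, W, reference = "H")
}
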