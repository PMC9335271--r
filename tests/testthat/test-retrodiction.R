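test_that("farey_best finds the simplest fraction within tolerance", {
  expect_equal(farey_best(0.5, 0.1)[c("p", "q")], list(p = 1, q = 2))
  expect_equal(farey_best(1.0, 0.01)[c("p", "q")], list(p = 1, q = 1))
  expect_equal(farey_best(0.4375, 0.01)[c("p", "q")], list(p = 7, q = 16))
  b <- farey_best(0.30, 0.15)
  expect_equal(b[c("p", "q")], list(p = 1, q = 3))
  expect_equal(b$error, abs(0.30 - 1 / 3) / 0.30)
  expect_error(farey_best(1.2, 0.1), "0, 1")
  expect_error(farey_best(0.5, 0), "positive")
})

test_that("farey_best error bound holds and tightens with tau", {
  set.seed(7)
  for (i in 1:200) {
    r <- runif(1, 0.05, 1)
    tau <- runif(1, 0.01, 0.2)
    b <- farey_best(r, tau)
    expect_lte(b$error, tau)
    expect_equal(chemspacer:::.gcd(b$p, b$q), 1)
    # decreasing tau never increases the achieved error
    b2 <- farey_best(r, tau / 2)
    expect_lte(b2$error, b$error)
  }
  # min-error variant returns the global optimum under the cap
  bm <- farey_best(0.30, 0.15, method = "min_error", max_order = 10)
  expect_equal(bm$value, 3 / 10)
})

test_that("rescale coefficients recover planted exact ratios", {
  # iron's H-relative weight doubled: multiplier 1/2 at any tau
  A <- perturb_weights(elements = "Fe", factors = 2, chemist = "t", year = 1819)
  for (tau in c(0.01, 0.1, 0.2)) {
    rc <- rescale_coefficient("Fe", A, tau)
    expect_equal(c(rc$num, rc$den), c(1, 2))
    expect_lte(rc$error, tau)
  }
  # identity system: multiplier 1 for every element at every tau
  id <- perturb_weights(chemist = "identity", year = 1850)
  for (e in c("H", "O", "Fe", "Cl"))
    expect_equal(with(rescale_coefficient(e, id, 0.01), c(num, den)), c(1, 1))
  # factor 7/16 on O: ratio 16/7 recovered as 2 + 2/7
  A2 <- perturb_weights(elements = "O", factors = 7 / 16, chemist = "t2",
                        year = 1850)
  rc2 <- rescale_coefficient("O", A2, 0.01)
  expect_equal(c(rc2$num, rc2$den), c(16, 7))
  # both hydrogen-relative ratios are reported and reciprocal
  expect_equal(rc2$wa * rc2$aw, 1)
  # a Dalton-style table (O = 7 on H = 1) splits into integer + Farey part
  dal <- weight_table("dalton_style", 1810, c(H = 1, O = 7))
  rcd <- rescale_coefficient("O", dal, 0.2)
  expect_gte(rcd$value, 2)
  expect_lte(rcd$error, 0.2)
  ob <- oracle_farey(rcd$wa - 2, 0.2)
  expect_equal(rcd$value - 2, ob$p / ob$q)
  expect_error(rescale_coefficient("Br", dal, 0.1), "untranslatable")
})

test_that("formula rescaling reproduces the iron-doubling correspondence", {
  A <- perturb_weights(elements = "Fe", factors = 2, chemist = "t", year = 1819)
  for (tau in seq(0.01, 0.20, by = 0.01))
    expect_identical(render_formula(rescale_formula("Fe2O3", A, tau)), "FeO3")
  # identity leaves (canonical) formulae unchanged, including non-reduced
  # empirical formulae such as C2H2Cl2
  id <- perturb_weights(chemist = "identity", year = 1850)
  for (s in c("H2O4S", "Fe2O3", "C2H6O", "C2Cl2H2"))
    expect_identical(render_formula(rescale_formula(s, id, 0.05)), s)
  # H2O with f(O) = 7/3: H2 O7/3 -> x3 -> H6O7
  A3 <- perturb_weights(elements = "O", factors = 3 / 7, chemist = "t3",
                        year = 1850)
  expect_identical(render_formula(rescale_formula("H2O", A3, 0.001)), "H6O7")
  # scale invariance: F and 2F rescale to the same normalized formula
  expect_identical(render_formula(rescale_formula("Fe4O6", A, 0.05)), "FeO3")
})

test_that("rescaling with the inverse table round-trips coefficient ratios", {
  A <- perturb_weights(elements = c("Fe", "O"), factors = c(2, 1 / 2),
                       chemist = "fwd", year = 1850)
  B <- perturb_weights(elements = c("Fe", "O"), factors = c(1 / 2, 2),
                       chemist = "back", year = 1850)
  f1 <- rescale_formula("Fe2O3", A, 0.001)
  f2 <- rescale_formula(render_formula(f1), B, 0.001)
  orig <- parse_formula("Fe2O3")
  expect_equal(f2$num / f2$num[1], orig$num / orig$num[1])
})

test_that("retro spaces drop untranslatable substances and keep the rest", {
  sp <- toy_space()
  id <- perturb_weights(chemist = "identity", year = 1861)
  rs <- retro_space(sp, id, 0.05)
  expect_equal(n_substances(rs), 13)
  expect_setequal(rs$substances$formula, snapshot(sp, 1860)$substances$formula)
  # a table without Br keeps no Br substance
  noBr <- perturb_weights(chemist = "noBr", year = 1861,
                          keep = c("C", "H", "O", "Na", "K", "Cl"))
  expect_message(rs2 <- retro_space(sp, noBr, 0.05), "dropped 5")
  expect_false(any(grepl("Br", rs2$substances$formula)))
  expect_equal(attr(rs2, "n_dropped"), 5)
})

test_that("retro scores: identity table gives tp 1; rates match set algebra", {
  sp <- toy_space()
  id <- perturb_weights(chemist = "identity", year = 1861)
  sc <- retro_scores(sp, id, 0.1, reference_year = 1868)
  expect_equal(sc$tp_rate, 1)
  p60 <- edge_set(sce_network(sp, 1860, weights = NULL))
  pref <- edge_set(sce_network(sp, 1868, weights = NULL))
  expect_equal(sc$fp_rate, length(setdiff(p60, pref)) / length(p60))
  expect_equal(sc$n_edges, length(p60))

  # perturbed weights: rates equal the explicit edge-set formulas
  A <- perturb_weights(elements = "K", factors = 3, chemist = "pk", year = 1861)
  sc2 <- retro_scores(sp, A, 0.05, reference_year = 1868)
  ptau <- edge_set(sce_network(retro_space(sp, A, 0.05), 1860, weights = NULL))
  expect_equal(sc2$tp_rate,
               length(intersect(ptau, pref)) / length(intersect(p60, pref)))
  expect_equal(sc2$fp_rate, length(setdiff(ptau, pref)) / length(ptau))

  sw <- retro_score_sweep(sp, id, taus = c(0.01, 0.1, 0.2))
  expect_equal(nrow(sw), 3)
  expect_true(all(sw$tp_rate == 1))
})

test_that("ordering agreement counts concordant pairs", {
  A <- c(H = 1, C = 12, O = 16, S = 32)
  expect_equal(ordering_agreement(A, A), 1)
  expect_equal(ordering_agreement(c(H = 1, C = 12, O = 16),
                                  c(H = 16, C = 12, O = 1)), 0)
  # one adjacent swap among 4 elements: 5 of 6 pairs concordant
  B <- c(H = 1, C = 16, O = 12, S = 32)
  expect_equal(ordering_agreement(A, B), 5 / 6)
  # ties discordant unless tied in both
  expect_equal(ordering_agreement(c(H = 1, C = 2), c(H = 1, C = 1)), 0)
  expect_equal(ordering_agreement(c(H = 1, C = 1), c(H = 2, C = 2)), 1)
  expect_error(ordering_agreement(c(H = 1), c(H = 1)), "two shared")
  # weight_table inputs work too
  wt1 <- weight_table("a", 1850, A)
  wt2 <- weight_table("b", 1850, B)
  expect_equal(ordering_agreement(wt1, wt2), 5 / 6)
})

test_that("weight tables validate and round-trip through delimited text", {
  expect_error(weight_table("x", 1850, c(H = -1)), "positive")
  expect_error(weight_table("x", 1850, c(O = 16)), "reference")
  wt <- perturb_weights(elements = "Fe", factors = 2, chemist = "rt",
                        year = 1819, keep = c("Fe", "O"))
  tmp <- tempfile(fileext = ".tsv")
  write_weight_table(wt, tmp)
  back <- read_weight_tables(tmp)[["rt"]]
  expect_equal(back$weights, wt$weights)
  expect_equal(back$year, wt$year)
  unlink(tmp)
  # shipped synthetic tables load
  dal <- read_weight_tables(system.file(
    "extdata", "weights_dalton_1810_synthetic.tsv", package = "chemspacer"))
  expect_equal(dal[[1]]$weights[["O"]], 7)
  expect_error(perturb_weights(elements = "Fe", factors = -2), "positive")
})
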