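test_that("network overlap: identity, disjoint, partial, bounds", {
  expect_equal(network_overlap(c("A->B", "C->D"), c("A->B", "C->D")), 1)
  expect_equal(network_overlap(c("A->B"), c("C->D")), 0)
  expect_equal(network_overlap(c("A->B", "C->D"), c("A->B", "E->F")), 0.5)
  expect_error(network_overlap(character(0), c("A->B")), "empty")
  # equals 1 iff subset
  expect_equal(network_overlap(c("A->B"), c("A->B", "C->D")), 1)
  expect_lt(network_overlap(c("A->B", "X->Y"), c("A->B", "C->D")), 1)
})

test_that("overlap matrix matches pairwise calls, column toward row", {
  nets <- sce_series(medium_space()$space, c(1820, 1840, 1868))
  m <- overlap_matrix(nets)
  expect_equal(unname(diag(m)), rep(1, 3))
  for (r in rownames(m)) for (c in colnames(m)) {
    if (r != c)
      expect_equal(m[r, c], network_overlap(nets[[c]], nets[[r]]),
                   info = paste(r, c))
  }
  expect_true(all(m >= 0 & m <= 1))
  # identical years give an all-ones matrix
  same <- list("1868" = nets[["1868"]], "1869" = nets[["1868"]])
  expect_true(all(overlap_matrix(same) == 1))
  expect_error(overlap_matrix(nets[1]), "two")
})

test_that("backbone applies the windowed-frequency rule strictly", {
  # hand-built yearly networks over a 10-year window ending 1810
  mk <- function(edges, nodes) {
    igraph::graph_from_data_frame(
      data.frame(from = sub("->.*", "", edges), to = sub(".*->", "", edges),
                 weight = 1, numerator = 1, denominator = 1),
      directed = TRUE, vertices = data.frame(name = nodes))
  }
  nodes <- c("A", "B", "C", "D")
  nets <- list()
  for (y in 1800:1810) {
    eds <- c("A->B")                        # present every year: 11/10 > 100%
    if (y == 1803) eds <- c(eds, "C->D")    # once in a 10-year window: 10%
    nets[[as.character(y)]] <- mk(eds, nodes)
  }
  bb60 <- backbone(nets, threshold = 60, end_year = 1810)
  expect_true("A->B" %in% paste0(bb60$i, "->", bb60$j))
  expect_false("C->D" %in% paste0(bb60$i, "->", bb60$j))
  expect_equal(bb60[bb60$i == "A", ]$frequency, 11)
  expect_equal(bb60[bb60$i == "A", ]$first_year, 1800)
  cd <- backbone(nets, threshold = 0, end_year = 1810)
  expect_equal(cd[cd$i == "C", ]$ubiquity_percent, 10)
  # threshold 0 keeps all ever-observed edges
  expect_setequal(paste0(cd$i, "->", cd$j), c("A->B", "C->D"))
  # zero-width window: edge between elements first appearing in the end year
  nets2 <- nets
  nets2[["1810"]] <- mk(c("A->B", "E->F"), c(nodes, "E", "F"))
  expect_message(bb2 <- backbone(nets2, threshold = 0, end_year = 1810),
                 "zero-width")
  expect_false("E->F" %in% paste0(bb2$i, "->", bb2$j))
})

test_that("backbone is monotone in the threshold", {
  nets <- sce_series(medium_space()$space, seq(1830, 1868, by = 2))
  key <- function(b) if (nrow(b) == 0) character(0) else paste0(b$i, "->", b$j)
  b100 <- key(backbone(nets, 100, 1868))
  b60 <- key(backbone(nets, 60, 1868))
  b0 <- key(backbone(nets, 0, 1868))
  expect_true(all(b100 %in% b60))
  expect_true(all(b60 %in% b0))
})

test_that("pair-level backbone reports both directions of qualifying pairs", {
  nets <- sce_series(medium_space()$space, seq(1830, 1868, by = 2))
  bd <- backbone(nets, 60, 1868)
  bp <- backbone(nets, 60, 1868, report = "pairs")
  # every directed qualifier appears, possibly joined by its reverse
  expect_true(all(paste0(bd$i, "->", bd$j) %in% paste0(bp$i, "->", bp$j)))
  expect_true(all(c("i", "j", "pair") %in% names(bp)))
})

test_that("ubiquity: degenerate full sample, determinism, stream stability", {
  g <- medium_space()
  sp <- g$space
  full <- edge_set(sce_network(sp, 1868, weights = NULL))
  u100 <- ubiquity(sp, 1868, sample_sizes = 100, reps = 5, seed = 1)
  expect_true(all(u100$count == 5))
  expect_setequal(u100$edge, full)

  u1 <- ubiquity(sp, 1868, sample_sizes = c(20, 60), reps = 10, seed = 42)
  u2 <- ubiquity(sp, 1868, sample_sizes = c(20, 60), reps = 10, seed = 42)
  expect_identical(u1, u2)
  # adding a sample size does not perturb existing replicates
  u3 <- ubiquity(sp, 1868, sample_sizes = c(20, 40, 60), reps = 10, seed = 42)
  expect_identical(u1[u1$sample_size == 20, ], u3[u3$sample_size == 20, ])
  expect_identical(u1[u1$sample_size == 60, ], u3[u3$sample_size == 60, ])
  # different seed, different draws
  u4 <- ubiquity(sp, 1868, sample_sizes = c(20, 60), reps = 10, seed = 43)
  expect_false(identical(u1$count, u4$count))

  expect_warning(ubiquity(sp, 1868, sample_sizes = 0.001, reps = 2, seed = 1),
                 "skipped")
})

test_that("mean edge appearance grows with sample size", {
  g <- medium_space()
  u <- ubiquity(g$space, 1868, sample_sizes = c(10, 40, 70, 95),
                reps = 15, seed = 5)
  means <- tapply(u$count, u$sample_size, mean)
  means <- means[order(as.numeric(names(means)))]
  # monotone on average; small fluctuations (< 5% of reps) tolerated because
  # the statement is statistical, not per-draw
  expect_true(all(diff(means) > -0.75))
  expect_gt(means[length(means)], means[1])
})
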