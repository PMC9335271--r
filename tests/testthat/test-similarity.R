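test_that("toy-space profiles match hand counts, including isomer multiplicity", {
  sp <- toy_space()
  fbr <- element_profile(sp, 1868, "Br")
  expect_equal(fbr$cardinality, 5)
  # the two C2H2Br2 isomers both contribute C2H2X2
  expect_equal(fbr$entries[fbr$entries$arranged == "C2H2X2", ]$mult, 2)
  fcl <- element_profile(sp, 1868, "Cl")
  expect_equal(fcl$cardinality, 5)
  expect_equal(element_profile(sp, 1868, "O")$cardinality, 3)
  # element in exactly one substance
  sp1 <- chemical_space(data.frame(id = 1:2, formula = c("FeO", "H2O"),
                                   year = 1850))
  expect_equal(element_profile(sp1, 1850, "Fe")$cardinality, 1)
  expect_error(element_profile(sp, 1825, "Br"), "does not occur")
})

test_that("every documented toy similarity is reproduced exactly", {
  sp <- toy_space()
  exp <- expected_toy()
  for (i in seq_len(nrow(exp))) {
    s <- similarity(sp, 1868, exp$source[i], exp$target[i])
    expect_equal(s$numerator, exp$numerator[i],
                 info = paste(exp$source[i], "->", exp$target[i]))
    expect_equal(s$denominator, exp$denominator[i])
    expect_equal(s$value, exp$numerator[i] / exp$denominator[i])
  }
  # all pairs absent from the fixture have similarity 0
  els <- elements_known(sp, 1868)
  listed <- paste(exp$source, exp$target)
  for (x in els) for (y in setdiff(els, x)) {
    if (!paste(x, y) %in% listed)
      expect_equal(similarity(sp, 1868, x, y)$value, 0,
                   info = paste(x, "->", y))
  }
})

test_that("similarity contracts: bounds, integer numerator, errors", {
  sp <- toy_space()
  expect_error(similarity(sp, 1868, "Br", "Br"), "distinct")
  s <- similarity(sp, 1868, "H", "Na")
  expect_true(s$value >= 0 && s$value <= 1)
  expect_equal(s$value * s$denominator, round(s$value * s$denominator))
  expect_error(similarity_quotient(1, 0), "positive")
  expect_error(similarity_quotient(5, 3), "cardinality")
})

test_that("full substitutability gives similarity 1", {
  # every Br formula has its Br->Cl substitution present
  sp <- chemical_space(data.frame(
    id = 1:4, formula = c("HBr", "HCl", "NaBr", "NaCl"), year = 1850))
  expect_equal(similarity(sp, 1850, "Br", "Cl")$value, 1)
})

test_that("similarity is local: unrelated substances leave it unchanged", {
  base <- data.frame(id = sprintf("a%d", 1:5),
                     formula = c("HBr", "HCl", "NaBr", "NaCl", "KBr"),
                     year = 1850)
  s0 <- similarity(chemical_space(base), 1850, "Br", "Cl")
  extra <- rbind(base, data.frame(id = "b1", formula = "Fe2O3", year = 1850))
  s1 <- similarity(chemical_space(extra), 1850, "Br", "Cl")
  expect_equal(s0$numerator, s1$numerator)
  expect_equal(s0$denominator, s1$denominator)
})

test_that("similarity equals the brute-force substitute-and-lookup oracle", {
  set.seed(99)
  for (rep in 1:20) {
    df <- random_space_df(sample(10:30, 1))
    sp <- chemical_space(df)
    els <- elements_known(sp, 1850)
    for (x in els) for (y in setdiff(els, x)) {
      o <- oracle_similarity(df, x, y)
      s <- similarity(sp, 1850, x, y)
      expect_equal(s$numerator, o$numerator, info = paste(rep, x, y))
      expect_equal(s$denominator, o$denominator)
    }
  }
})

test_that("most_similar returns the argmax set with ties, empty at max 0", {
  sp <- toy_space()
  expect_identical(most_similar(sp, 1868, "Br"), "Cl")
  expect_identical(most_similar(sp, 1868, "K"), c("H", "Na"))  # exact tie
  expect_identical(most_similar(sp, 1868, "O"), character(0))
  expect_identical(most_similar(sp, 1868, "C"), character(0))
})

test_that("SCE networks have max-similarity edges and ranked nodes", {
  sp <- toy_space()
  g <- sce_network(sp, 1868)
  expect_s3_class(g, "igraph")
  expect_setequal(edge_set(g),
                  c("Br->Cl", "Cl->Br", "Na->H", "K->H", "K->Na", "H->Na"))
  expect_equal(igraph::graph_attr(g, "year"), 1868L)
  # out-edges of one node all carry the same maximal weight; no self loops
  el <- igraph::as_data_frame(g)
  for (src in unique(el$from)) {
    w <- el$weight[el$from == src]
    expect_true(all(w == max(w)) && all(w > 0))
  }
  expect_false(any(el$from == el$to))
  # node attributes: substance counts and ascending atomic-weight ranks
  v <- igraph::as_data_frame(g, what = "vertices")
  expect_equal(v$n_substances[v$name == "H"], 7)
  expect_equal(v$name[order(v$aw_rank)][1], "H")  # lightest element ranks first

  # three elements, one of which shares nothing: exactly 2 edges
  chain <- chemical_space(data.frame(
    id = 1:2, formula = c("HBr", "HCl"), year = 1850))
  expect_setequal(edge_set(sce_network(chain, 1850)),
                  c("Br->Cl", "Cl->Br"))

  # one-element space: no edges
  uni <- chemical_space(data.frame(id = 1, formula = "O2", year = 1850))
  expect_length(edge_set(sce_network(uni, 1850)), 0)

  # element missing from the weight table: kept, rank NA, warning
  w <- c(H = 1.008, O = 15.999)
  expect_warning(g2 <- sce_network(chemical_space(data.frame(
    id = 1:2, formula = c("H2O", "FeO"), year = 1850)), 1850, weights = w),
    "Fe")
  v2 <- igraph::as_data_frame(g2, what = "vertices")
  expect_true(is.na(v2$aw_rank[v2$name == "Fe"]))
})

test_that("network exports are readable", {
  sp <- toy_space()
  g <- sce_network(sp, 1868)
  f1 <- tempfile(fileext = ".graphml")
  write_sce_graphml(g, f1)
  g2 <- igraph::read_graph(f1, format = "graphml")
  expect_setequal(edge_set(g2), edge_set(g))
  f2 <- tempfile(fileext = ".json")
  write_sce_json(g, f2)
  j <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(j$year, 1868)
  expect_setequal(paste0(j$edges$source, "->", j$edges$target), edge_set(g))
  unlink(c(f1, f2))
})
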