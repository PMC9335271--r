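# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

# 12 elements in 4 planted families, all available from the start: the
# configuration in which full template sharing makes within-family
# similarities exact ties, so every planted directed pair is an SCE edge.
recovery_config <- function(seed = 7, base_count = 4, growth = 1.047) {
  roster <- data.frame(
    element = c("Li", "Na", "K", "F", "Cl", "Br", "O", "S", "Se",
                "Fe", "Co", "Ni"),
    intro_year = 1800L,
    family = rep(c("alkali", "halogens", "chalcogens", "iron"), each = 3))
  space_config(years = c(1800L, 1868L), roster = roster,
               base_count = base_count, growth = growth, seed = seed)
}

# small two-family roster for fast structural tests
two_family_config <- function(seed = 3, years = c(1800L, 1810L), ...) {
  roster <- data.frame(element = c("Na", "K", "Cl", "Br"),
                       intro_year = 1800L,
                       family = c("f1", "f1", "f2", "f2"))
  space_config(years = years, roster = roster, base_count = 6,
               growth = 1.05, seed = seed, ...)
}

# moderate synthetic space reused across convergence tests
medium_space <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_space(recovery_config(seed = 11, base_count = 2,
                                               growth = 1.04))
    cache
  }
})

expected_toy <- function() {
  read.csv(system.file("extdata", "toy_expected_similarities.csv",
                       package = "chemspacer"), stringsAsFactors = FALSE)
}
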