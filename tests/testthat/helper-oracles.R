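# Independent oracles, deliberately implemented with different machinery
# than the package (plain named vectors and loops, no data.table), so that
# agreement is evidence rather than tautology.

# tokenize a plain integer-coefficient formula into a named coefficient vector
oracle_comp <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  sym <- sub("[0-9]*$", "", toks)
  n <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  n[is.na(n)] <- 1
  tapply(n, sym, sum)
}

# arranged formula by direct string surgery on the coefficient vector
oracle_arrange <- function(s, e) {
  v <- oracle_comp(s)
  names(v)[names(v) == e] <- "X"
  v <- v[order(names(v))]
  paste0(names(v), ifelse(v == 1, "", v), collapse = "")
}

# brute-force substitutability: loop over x-substances, test arranged-string
# membership in the set of y-substances' arranged strings
oracle_similarity <- function(df, x, y) {
  has <- function(s, e) e %in% names(oracle_comp(s))
  fx <- df$formula[vapply(df$formula, has, logical(1), e = x)]
  fy <- df$formula[vapply(df$formula, has, logical(1), e = y)]
  if (length(fx) == 0) stop("empty profile")
  ax <- vapply(fx, oracle_arrange, character(1), e = x)
  ay <- unique(vapply(fy, oracle_arrange, character(1), e = y))
  list(numerator = sum(ax %in% ay), denominator = length(ax),
       value = mean(ax %in% ay))
}

# exhaustive best-Farey search over denominators <= qmax
oracle_farey <- function(r, tau, qmax = 50) {
  best <- NULL
  for (q in 1:qmax) for (p in 1:q) {
    err <- abs(r - p / q) / r
    if (err <= tau) {
      g <- chemspacer:::.gcd(p, q)
      cand <- list(p = p / g, q = q / g, error = err)
      if (is.null(best) || cand$q < best$q ||
          (cand$q == best$q && cand$error < best$error)) best <- cand
    }
  }
  best
}

# random substance tables for oracle cross-checks (independent of the
# package's planted-family generator)
random_space_df <- function(n, elements = c("C", "H", "O", "N", "Cl", "Br", "Na", "S"),
                            isomer_p = 0.2) {
  formulas <- character(n)
  for (i in seq_len(n)) {
    if (i > 1 && runif(1) < isomer_p) {
      formulas[i] <- formulas[sample.int(i - 1, 1)]
    } else {
      k <- sample(1:4, 1)
      sym <- sample(elements, k)
      coef <- sample(1:4, k, replace = TRUE)
      o <- order(sym)
      formulas[i] <- paste0(sym[o], ifelse(coef[o] == 1, "", coef[o]),
                            collapse = "")
    }
  }
  data.frame(id = sprintf("R%03d", seq_len(n)), formula = formulas,
             year = 1850L)
}
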