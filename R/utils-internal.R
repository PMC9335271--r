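# Internal numeric helpers: exact rationals held as doubles (all integers kept
# well below 2^53, so arithmetic is exact), decimal big integers as digit
# vectors, and reproducible RNG substreams.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.lcm <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  a / .gcd(a, b) * b
}

# reduced rational p/q with q > 0
.rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}

.rat_mul <- function(a, b) .rat(a$num * b$num, a$den * b$den)
.rat_add <- function(a, b) .rat(a$num * b$den + b$num * a$den, a$den * b$den)
.rat_value <- function(a) a$num / a$den

.rat_render <- function(num, den) {
  if (den == 1) as.character(num) else paste0(num, "/", den)
}

# Big non-negative integers as little-endian digit vectors (base 10), used
# only for exact 2^n - n - 1 where doubles lose integer exactness.
.big_from_int <- function(n) {
  if (n == 0) return(0L)
  d <- integer(0)
  while (n > 0) { d <- c(d, as.integer(n %% 10)); n <- n %/% 10 }
  d
}

.big_double <- function(d) {
  d <- d * 2L
  carry <- 0L
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% 10L
    carry <- v %/% 10L
  }
  while (carry > 0L) { d <- c(d, carry %% 10L); carry <- carry %/% 10L }
  d
}

.big_sub_small <- function(d, m) {
  # d - m for small non-negative integer m, result assumed non-negative
  s <- .big_from_int(m)
  s <- c(s, integer(max(0L, length(d) - length(s))))
  borrow <- 0L
  for (i in seq_along(d)) {
    v <- d[i] - s[i] - borrow
    if (v < 0L) { v <- v + 10L; borrow <- 1L } else borrow <- 0L
    d[i] <- v
  }
  if (borrow > 0L) stop("negative big-integer result")
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  d
}

.big_render <- function(d) paste(rev(d), collapse = "")

# Deterministic substream seed derived from a master seed and up to two
# indices; keeps values in the 32-bit signed range so set.seed() accepts them.
.substream <- function(master, a = 0L, b = 0L) {
  m <- as.numeric(master) %% 50021
  as.integer((m * 40503 + as.numeric(a) * 100003 + as.numeric(b) * 101) %% 2147483629)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
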