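# Naive piecewise oracles for the ECDF statistics. Deliberately built on a
# different route than the package (pointwise ECDF evaluation mean(v <= t)
# instead of pooled rank/cumsum algebra). Valid for tie-free inputs, which
# is what the random continuous fixtures produce.

o_ecdf <- function(v) function(t) vapply(t, function(ti) mean(v <= ti),
                                         numeric(1))

oracle_ks <- function(x, y) {
  z <- sort(unique(c(x, y)))
  max(abs(o_ecdf(x)(z) - o_ecdf(y)(z)))
}

oracle_kuiper <- function(x, y) {
  z <- sort(unique(c(x, y)))
  d <- o_ecdf(x)(z) - o_ecdf(y)(z)
  max(0, d) + max(0, -d)
}

oracle_wass <- function(x, y) {
  z <- sort(unique(c(x, y)))
  L <- length(z)
  if (L < 2) return(0)
  d <- abs(o_ecdf(x)(z) - o_ecdf(y)(z))
  sum(d[-L] * diff(z))
}

oracle_dts <- function(x, y) {
  z <- sort(unique(c(x, y)))
  L <- length(z)
  if (L < 2) return(0)
  d <- abs(o_ecdf(x)(z) - o_ecdf(y)(z))
  fp <- o_ecdf(c(x, y))(z)
  w <- ifelse(fp > 0 & fp < 1, 1 / sqrt(fp * (1 - fp)), 0)
  sum((d * w)[-L] * diff(z))
}

# Sum over all pooled observations of the squared ECDF difference,
# scaled by nm/N^2 (equivalent to the rank form when there are no ties).
oracle_cvm <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  z <- sort(c(x, y))
  d <- o_ecdf(x)(z) - o_ecdf(y)(z)
  n * m / N^2 * sum(d^2)
}

oracle_ad <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  z <- sort(c(x, y))
  k <- seq_len(N - 1)
  M <- n * o_ecdf(x)(z[k])  # x-count among the k smallest pooled values
  sum((M * N - n * k)^2 / (k * (N - k))) / (n * m)
}

oracle_for <- list(ks = oracle_ks, kuiper = oracle_kuiper,
                   wass = oracle_wass, dts = oracle_dts,
                   cvm = oracle_cvm, ad = oracle_ad)

# Tie-free random sample pair of sizes 2..max_n each.
random_pair <- function(max_n = 50) {
  n <- sample(2:max_n, 1)
  m <- sample(2:max_n, 1)
  if (runif(1) < 0.5) {
    list(x = rnorm(n), y = rnorm(m, mean = runif(1, -1, 1)))
  } else {
    list(x = runif(n, 0, 3), y = runif(m, 0.5, 4))
  }
}
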