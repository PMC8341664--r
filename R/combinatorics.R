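# Minimal arbitrary-precision non-negative integers for the counting
# utilities: little-endian limbs in base 1e6 stored as doubles, so every
# intermediate product stays far below 2^53. Only what binomial products
# need: multiply/divide by a small integer, full multiply, decimal print.

.BI_BASE <- 1e6

.bi_new <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  limbs
}

# Single carry pass; limb values may temporarily exceed the base (they
# stay below 2^53 by construction of the callers).
.bi_carry <- function(a) {
  out <- numeric(length(a))
  carry <- 0
  for (i in seq_along(a)) {
    v <- a[i] + carry
    out[i] <- v %% .BI_BASE
    carry <- v %/% .BI_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% .BI_BASE)
    carry <- carry %/% .BI_BASE
  }
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

.bi_mul_small <- function(a, m) {
  stopifnot(m >= 0, m == floor(m), m < 2^31)
  if (m == 0) return(0)
  .bi_carry(a * m)
}

# Exact division by a small integer (remainder must be zero).
.bi_div_small <- function(a, d) {
  stopifnot(d >= 1, d == floor(d))
  out <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    v <- rem * .BI_BASE + a[i]
    out[i] <- v %/% d
    rem <- v %% d
  }
  stopifnot(rem == 0)
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

# Schoolbook product; each accumulated limb stays below
# length(a) * (base - 1)^2 < 2^53 for operands up to ~9000 limbs.
.bi_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    rng <- i:(i + length(b) - 1L)
    out[rng] <- out[rng] + a[i] * b
  }
  .bi_carry(out)
}

.bi_to_string <- function(a) {
  s <- sprintf("%06.0f", rev(a))
  s[1L] <- sprintf("%.0f", a[length(a)])
  paste(s, collapse = "")
}

.bi_log10 <- function(a) {
  nl <- length(a)
  top <- 0
  for (i in nl:max(1L, nl - 3L)) top <- top * .BI_BASE + a[i]
  log10(top) + 6 * (max(1L, nl - 3L) - 1L)
}

# Exact binomial coefficient via the multiplicative formula; every
# intermediate division is exact.
.bi_choose <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) return(.bi_new(0))
  k <- min(k, n - k)
  acc <- .bi_new(1)
  if (k == 0) return(acc)
  for (i in seq_len(k)) {
    acc <- .bi_mul_small(acc, n - k + i)
    acc <- .bi_div_small(acc, i)
  }
  acc
}

#' Number of unique pairwise distances
#'
#' The `n (n - 1) / 2` distinct distances among `n` data points -- the
#' quantity whose quadratic growth motivates downsampling before any
#' distance-matrix-based analysis.
#'
#' @param n positive integer number of instances.
#' @return The exact count as a double (exact for all counts below 2^53).
#' @examples
#' count_pairwise_distances(150)  # 11175
#' @export
count_pairwise_distances <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  n * (n - 1) / 2
}

#' Number of class-proportional subsample combinations
#'
#' The exact size of the search space of class-proportional sampling: the
#' product over classes of `choose(class_size, draw_count)`, where each
#' class's draw count is `round(fraction * class_size)` (ties to even).
#' Computed in exact arbitrary-precision arithmetic, since already modest
#' class sizes push the count beyond double precision.
#'
#' @param class_sizes positive integer vector of per-class instance counts.
#' @param fraction sampled fraction in `[0, 1]`.
#' @return An object of class `combination_count`: `exact` (decimal digit
#'   string), `log10` (consistent with `exact`), `value` (double
#'   approximation, `Inf` beyond double range), `draws` (per-class draw
#'   counts).
#' @examples
#' count_class_proportional_combinations(c(50, 50, 50), 0.5)
#' @export
count_class_proportional_combinations <- function(class_sizes, fraction) {
  if (length(class_sizes) < 1L) stop("empty class list", call. = FALSE)
  if (any(class_sizes < 1 | class_sizes != floor(class_sizes))) {
    stop("class sizes must be positive integers", call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) {
    stop("'fraction' must lie in [0, 1]", call. = FALSE)
  }
  draws <- round(fraction * class_sizes)
  acc <- .bi_new(1)
  for (i in seq_along(class_sizes)) {
    acc <- .bi_mul(acc, .bi_choose(class_sizes[i], draws[i]))
  }
  s <- .bi_to_string(acc)
  structure(
    list(exact = s, log10 = .bi_log10(acc), value = as.numeric(s),
         draws = as.integer(draws)),
    class = "combination_count"
  )
}

#' @export
print.combination_count <- function(x, ...) {
  cat(sprintf("<combination_count: %s (= %.9e, log10 = %.6f)>\n",
              x$exact, x$value, x$log10))
  invisible(x)
}

#' Combination counts over a grid of sampled fractions
#'
#' Evaluates [count_class_proportional_combinations()] for each fraction.
#' For symmetric class sizes the curve is bell-shaped with its maximum at
#' a 50% fraction, and `count(f) = count(1 - f)` whenever the per-class
#' draw counts are complementary.
#'
#' @param class_sizes positive integer vector of per-class counts.
#' @param fractions numeric vector of fractions in `[0, 1]`.
#' @return A data frame with columns `fraction`, `log10_count`, `exact`.
#' @export
combination_curve <- function(class_sizes, fractions) {
  rows <- lapply(fractions, function(f) {
    cc <- count_class_proportional_combinations(class_sizes, f)
    data.frame(fraction = f, log10_count = cc$log10, exact = cc$exact,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
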