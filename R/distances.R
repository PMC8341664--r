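#' Metric tokens
#'
#' The nine distribution-distance tokens accepted throughout the package
#' (case-insensitively): six empirical-CDF statistics computed on raw values
#' (`"ad"`, `"kuiper"`, `"cvm"`, `"wass"`, `"dts"`, `"ks"`) and three
#' density-based distances computed on smoothed-data-histogram estimates
#' sharing the full data's grid (`"kld"`, `"euc"`, `"amrdd"`).
#'
#' All nine are dissimilarities: smaller means more similar, and the raw
#' statistic (never a p-value) is used, since subset selection only needs an
#' argmin.
#'
#' @return Character vector of the nine tokens.
#' @export
metric_ids <- function() {
  c("ad", "kuiper", "cvm", "wass", "dts", "ks", "kld", "euc", "amrdd")
}

.ecdf_metrics <- c("ad", "kuiper", "cvm", "wass", "dts", "ks")
.pdf_metrics <- c("kld", "euc", "amrdd")

.match_metric <- function(metric_id) {
  m <- tolower(as.character(metric_id)[1L])
  if (!m %in% metric_ids()) {
    stop("unknown metric '", metric_id, "'; legal tokens are: ",
         paste(metric_ids(), collapse = ", "), call. = FALSE)
  }
  m
}

.check_pair <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing value in input", call. = FALSE)
}

# ---- pooled-sample machinery ------------------------------------------------
# All six ECDF statistics work on the pooled sorted values `z` plus the
# indicator `isx` of which pooled element came from the first sample.

.pooled_order <- function(x, y) {
  n <- length(x)
  v <- c(x, y)
  o <- order(v)
  list(z = v[o], isx = o <= n)
}

# Merge two already-sorted vectors; avoids re-sorting the (large, fixed)
# second sample in the trial loop. Tie order between the vectors is
# irrelevant: the cores evaluate at tie-block ends or midrank-average.
.pooled_merge <- function(xs, ys) {
  n <- length(xs)
  N <- n + length(ys)
  pos <- findInterval(xs, ys) + seq_len(n)
  z <- numeric(N)
  isx <- logical(N)
  z[pos] <- xs
  isx[pos] <- TRUE
  z[!isx] <- ys
  list(z = z, isx = isx)
}

# TRUE at the last position of each tie block of the sorted vector z.
.block_ends <- function(z) {
  N <- length(z)
  if (N == 1L) return(TRUE)
  c(z[-N] != z[-1L], TRUE)
}

# Replace v by its mean within each tie block of z (midrank convention).
.block_average <- function(z, v) {
  N <- length(z)
  ends <- which(.block_ends(z))
  cnt <- diff(c(0L, ends))
  means <- diff(c(0, cumsum(v)[ends])) / cnt
  rep(means, cnt)
}

.core_ks <- function(z, isx, n, m) {
  keep <- .block_ends(z)
  cx <- cumsum(isx)[keep] / n
  cy <- cumsum(!isx)[keep] / m
  max(abs(cx - cy))
}

.core_kuiper <- function(z, isx, n, m) {
  keep <- .block_ends(z)
  d <- cumsum(isx)[keep] / n - cumsum(!isx)[keep] / m
  max(0, d) + max(0, -d)
}

.core_wass <- function(z, isx, n, m) {
  keep <- .block_ends(z)
  zk <- z[keep]
  L <- length(zk)
  if (L < 2L) return(0)
  d <- cumsum(isx)[keep] / n - cumsum(!isx)[keep] / m
  sum(abs(d[-L]) * diff(zk))
}

.core_dts <- function(z, isx, n, m) {
  N <- n + m
  keep <- .block_ends(z)
  zk <- z[keep]
  L <- length(zk)
  if (L < 2L) return(0)
  d <- abs(cumsum(isx)[keep] / n - cumsum(!isx)[keep] / m)
  fp <- which(keep) / N  # pooled ECDF at the block ends
  w <- 1 / sqrt(fp * (1 - fp))
  w[fp <= 0 | fp >= 1] <- 0  # endpoint exclusion
  sum((d * w)[-L] * diff(zk))
}

.core_ad <- function(z, isx, n, m) {
  N <- n + m
  xfrac <- as.numeric(isx)
  if (anyDuplicated(z)) xfrac <- .block_average(z, xfrac)
  M <- cumsum(xfrac)[-N]
  k <- seq_len(N - 1L)
  sum((M * N - n * k)^2 / (k * (N - k))) / (n * m)
}

.core_cvm <- function(z, isx, n, m) {
  N <- n + m
  r <- as.numeric(seq_len(N))
  if (anyDuplicated(z)) r <- .block_average(z, r)  # midranks
  rx <- r[isx]
  ry <- r[!isx]
  U <- n * sum((rx - seq_len(n))^2) + m * sum((ry - seq_len(m))^2)
  U / (n * m * N) - (4 * n * m - 1) / (6 * N)
}

.ecdf_cores <- list(ks = .core_ks, kuiper = .core_kuiper, wass = .core_wass,
                    dts = .core_dts, ad = .core_ad, cvm = .core_cvm)

.ecdf_stat <- function(x, y, metric) {
  .check_pair(x, y)
  po <- .pooled_order(x, y)
  .ecdf_cores[[metric]](po$z, po$isx, length(x), length(y))
}

# ---- ECDF statistics --------------------------------------------------------

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum-norm distance between the two empirical CDFs (right-continuous,
#' evaluated at the pooled jump points); lies in `[0, 1]`.
#'
#' @param x,y non-empty numeric vectors.
#' @return A single non-negative number.
#' @examples
#' ks_stat(c(1, 3), c(2, 4))  # 0.5
#' @export
ks_stat <- function(x, y) .ecdf_stat(x, y, "ks")

#' Two-sample Kuiper statistic
#'
#' `V = sup(F1 - F2) + sup(F2 - F1)`, in `[0, 2]`. Unlike the
#' Kolmogorov-Smirnov statistic it weights deviations on both flanks.
#'
#' @inheritParams ks_stat
#' @return A single non-negative number.
#' @export
kuiper_stat <- function(x, y) .ecdf_stat(x, y, "kuiper")

#' Two-sample Cramer-von Mises statistic
#'
#' Rank-based form
#' `T = U / (n m (n+m)) - (4 m n - 1) / (6 (m+n))` with
#' `U = n * sum((r_i - i)^2) + m * sum((s_j - j)^2)` over the midranks of
#' the two samples in the pooled ordering (ties averaged).
#'
#' @inheritParams ks_stat
#' @return A single number (non-negative up to the rank-form minimum).
#' @export
cvm_stat <- function(x, y) .ecdf_stat(x, y, "cvm")

#' Two-sample Anderson-Darling statistic
#'
#' `A^2 = (1/(n m)) * sum_{k=1}^{N-1} (M_k N - n k)^2 / (k (N-k))` with
#' `N = n + m` and `M_k` the number of first-sample observations among the
#' `k` smallest pooled values; ties are resolved by the midrank convention
#' (tied blocks contribute fractionally). Tail deviations get heavy weight,
#' which is what makes this statistic sensitive to stray extreme values.
#'
#' @inheritParams ks_stat
#' @return A single number.
#' @examples
#' ad_stat(c(1, 3), c(2, 4))  # 2/3
#' @export
ad_stat <- function(x, y) .ecdf_stat(x, y, "ad")

#' Two-sample 1-Wasserstein distance
#'
#' Exact `integral |F1 - F2| dt` over the pooled order statistics (sum of
#' absolute ECDF differences times interval lengths). For a pure translation
#' of equal-sized samples it equals the shift.
#'
#' @inheritParams ks_stat
#' @return A single non-negative number, in the units of the data.
#' @export
wasserstein_stat <- function(x, y) .ecdf_stat(x, y, "wass")

#' Variance-weighted ECDF distance (DTS)
#'
#' `integral |F1 - F2| / sqrt(Fp (1 - Fp)) dt` with `Fp` the pooled ECDF
#' evaluated on each inter-point interval; intervals where `Fp` is 0 or 1
#' are excluded. The weight inflates tail discrepancies relative to central
#' ones of the same unweighted area.
#'
#' @inheritParams ks_stat
#' @return A single non-negative number.
#' @export
dts_stat <- function(x, y) .ecdf_stat(x, y, "dts")

# ---- PDF distances ----------------------------------------------------------

.check_pdf_pair <- function(p, q) {
  stopifnot(inherits(p, "density_estimate"), inherits(q, "density_estimate"))
  if (!.same_grid(p, q)) stop("mismatched grids", call. = FALSE)
}

#' Euclidean distance between two densities on a shared grid
#'
#' @param p,q `density_estimate` objects on the same grid.
#' @return The l2 norm of the elementwise density difference.
#' @export
euclidean_pdf_dist <- function(p, q) {
  .check_pdf_pair(p, q)
  sqrt(sum((p$density - q$density)^2))
}

#' Symmetrised Kullback-Leibler divergence between two densities
#'
#' `KL(p||q) + KL(q||p)` over the kernel masses (`density * bin_width`),
#' after flooring both mass vectors at `eps` and renormalising so that empty
#' kernels do not produce infinities.
#'
#' @inheritParams euclidean_pdf_dist
#' @param eps mass floor (default `1e-12`).
#' @return A single non-negative number.
#' @export
kld_sym_dist <- function(p, q, eps = 1e-12) {
  .check_pdf_pair(p, q)
  pm <- pmax(p$density * p$bin_width, eps)
  qm <- pmax(q$density * q$bin_width, eps)
  pm <- pm / sum(pm)
  qm <- qm / sum(qm)
  sum((pm - qm) * log(pm / qm))
}

#' Absolute mean relative density difference
#'
#' Mean over the kernels of `|p_i - q_i| / (0.5 (p_i + q_i))`; a kernel
#' where both densities vanish contributes 0.
#'
#' @inheritParams euclidean_pdf_dist
#' @return A single number in `[0, 2]`.
#' @export
amrdd_dist <- function(p, q) {
  .check_pdf_pair(p, q)
  num <- abs(p$density - q$density)
  den <- 0.5 * (p$density + q$density)
  d <- ifelse(den == 0, 0, num / den)
  mean(d)
}

# ---- dispatch ---------------------------------------------------------------

#' Distance between a sample's distribution and the full data's
#'
#' Dispatches on the metric token: ECDF metrics operate on the raw values;
#' PDF metrics build smoothed-data-histogram estimates of both vectors on
#' the full column's grid (so the two densities are directly comparable)
#' and compare those. A constant full column is perfectly preserved by any
#' subset and yields distance 0 for every metric.
#'
#' @param sample_col numeric vector drawn from `full_col` (values within the
#'   full column's range).
#' @param full_col numeric vector of the full data's variable.
#' @param metric_id one of [metric_ids()].
#' @param grid optional precomputed `sdh_grid` of the full column (PDF
#'   metrics only); built on the fly when absent.
#' @return A single non-negative number; smaller means more similar.
#' @examples
#' compare_distributions(c(1, 3), c(1, 2, 3, 4), "ks")
#' @export
compare_distributions <- function(sample_col, full_col, metric_id = "ad",
                                  grid = NULL) {
  metric <- .match_metric(metric_id)
  .check_pair(sample_col, full_col)
  if (min(full_col) == max(full_col)) return(0)
  if (metric %in% .ecdf_metrics) {
    return(.ecdf_stat(sample_col, full_col, metric))
  }
  if (is.null(grid)) grid <- make_grid(full_col)
  p <- estimate_pdf(sample_col, grid)
  q <- estimate_pdf(full_col, grid)
  switch(metric,
         kld = kld_sym_dist(p, q),
         euc = euclidean_pdf_dist(p, q),
         amrdd = amrdd_dist(p, q))
}
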