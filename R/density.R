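#' Kernel grid over a variable's range
#'
#' Builds the fixed grid on which smoothed-data-histogram densities are
#' evaluated: `n_kernels` equally spaced centers spanning the minimum to the
#' maximum of a reference variable. Densities of a subsample and of the full
#' data must be computed on the *full* data's grid so they are comparable;
#' a subsample lies inside the full range by construction.
#'
#' A constant reference variable has zero range; the grid then degenerates
#' to a single support point carrying unit mass.
#'
#' @param reference_values non-empty numeric vector whose range defines the
#'   grid.
#' @param n_kernels number of kernel centers (default 200).
#' @return An object of class `sdh_grid`: `centers` (increasing, equally
#'   spaced), `bin_width` (spacing; 1 by convention for a degenerate grid)
#'   and `degenerate` (logical).
#' @examples
#' g <- make_grid(c(0, 10))
#' g$bin_width  # 10 / 199
#' @export
make_grid <- function(reference_values, n_kernels = 200L) {
  if (length(reference_values) < 1L) stop("empty reference vector",
                                          call. = FALSE)
  if (anyNA(reference_values)) stop("missing value in reference vector",
                                    call. = FALSE)
  n_kernels <- as.integer(n_kernels)
  if (n_kernels < 2L) stop("'n_kernels' must be at least 2", call. = FALSE)
  lo <- min(reference_values)
  hi <- max(reference_values)
  if (lo == hi) {
    return(structure(list(centers = lo, bin_width = 1, degenerate = TRUE),
                     class = "sdh_grid"))
  }
  structure(
    list(centers = seq(lo, hi, length.out = n_kernels),
         bin_width = (hi - lo) / (n_kernels - 1L),
         degenerate = FALSE),
    class = "sdh_grid"
  )
}

#' Smoothed-data-histogram density on a fixed grid
#'
#' Estimates a probability density at the kernel centers of a [make_grid()]
#' grid by the smoothed-data-histogram construction: every data point votes
#' for its `s` nearest kernel centers with linearly decreasing rank weights
#' `s, s-1, ..., 1` (distance ties broken toward the lower-index center).
#' Accumulated weights are normalised so the Riemann sum
#' `sum(density) * bin_width` equals 1, making density vectors comparable
#' across sample sizes.
#'
#' @param values non-empty numeric vector; every value must lie within one
#'   bin width of the grid's span (guaranteed when the grid was built from a
#'   superset of `values`).
#' @param grid an `sdh_grid`.
#' @param smoothing_s number of nearest kernels each point votes for
#'   (default 20, i.e., 10% of the default 200-kernel grid); capped at the
#'   number of kernels.
#' @return An object of class `density_estimate`: `centers`, `density`
#'   (non-negative, unit Riemann sum) and `bin_width`.
#' @examples
#' g <- make_grid(0:10, n_kernels = 23)
#' d <- estimate_pdf(runif(100, 0, 10), g)
#' sum(d$density) * d$bin_width  # 1
#' @export
estimate_pdf <- function(values, grid, smoothing_s = 20L) {
  stopifnot(inherits(grid, "sdh_grid"))
  if (length(values) < 1L) stop("empty values", call. = FALSE)
  smoothing_s <- as.integer(smoothing_s)
  if (smoothing_s < 1L) stop("'smoothing_s' must be positive", call. = FALSE)
  if (grid$degenerate) {
    if (any(abs(values - grid$centers) > grid$bin_width)) {
      stop("values outside the degenerate grid's support", call. = FALSE)
    }
    return(structure(list(centers = grid$centers, density = 1,
                          bin_width = grid$bin_width),
                     class = "density_estimate"))
  }
  K <- length(grid$centers)
  s <- min(smoothing_s, K)
  bw <- grid$bin_width
  u <- (values - grid$centers[1L]) / bw  # grid coordinates, in [0, K-1]
  if (any(u < -1 | u > K)) {
    stop("values outside the grid's range", call. = FALSE)
  }
  w <- numeric(K)
  offs <- seq.int(-s, s)
  wts <- as.numeric(s:1)
  base <- floor(u)
  for (i in seq_along(u)) {
    j <- base[i] + offs            # candidate center indices, 0-based
    d <- abs(u[i] - j)
    d[j < 0 | j > K - 1] <- Inf    # outside the grid
    ord <- order(d, j)[seq_len(s)] # ties toward the lower-index center
    jj <- j[ord] + 1L
    w[jj] <- w[jj] + wts
  }
  structure(
    list(centers = grid$centers, density = w / (sum(w) * bw),
         bin_width = bw),
    class = "density_estimate"
  )
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate: %d kernels on [%g, %g]>\n",
              length(x$centers), min(x$centers), max(x$centers)))
  invisible(x)
}

# Shared-grid check for the PDF-based distances.
.same_grid <- function(p, q) {
  length(p$centers) == length(q$centers) &&
    isTRUE(all.equal(p$centers, q$centers, tolerance = 1e-12)) &&
    isTRUE(all.equal(p$bin_width, q$bin_width, tolerance = 1e-12))
}
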