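#' Specification of a one-dimensional Gaussian mixture
#'
#' Describes the class-labelled univariate Gaussian mixtures used as
#' benchmark fixtures. Two readings of the class sizes are supported:
#' `"priors"` mode draws class memberships multinomially from the prior
#' weights, `"fixed"` mode uses explicit per-class counts.
#'
#' @param priors class prior weights (simplex; must sum to 1).
#' @param means,sds per-class Gaussian means and positive standard
#'   deviations, same length as `priors`.
#' @param n_total total number of instances.
#' @param mode `"priors"` (multinomial class sizes, the default) or
#'   `"fixed"` (explicit counts).
#' @param counts per-class counts, required in `"fixed"` mode and summing
#'   to `n_total`.
#' @return An object of class `gmm_spec`.
#' @seealso [default_gmm1d_spec()] for the canonical three-class fixture.
#' @export
gmm_spec <- function(priors, means, sds, n_total,
                     mode = c("priors", "fixed"), counts = NULL) {
  mode <- match.arg(mode)
  k <- length(priors)
  if (length(means) != k || length(sds) != k) {
    stop("'priors', 'means' and 'sds' must have equal length", call. = FALSE)
  }
  if (abs(sum(priors) - 1) > 1e-12) stop("'priors' must sum to 1",
                                         call. = FALSE)
  if (any(sds <= 0)) stop("'sds' must be positive", call. = FALSE)
  n_total <- as.integer(n_total)
  if (n_total < 1L) stop("'n_total' must be positive", call. = FALSE)
  if (mode == "fixed") {
    if (is.null(counts)) stop("'fixed' mode requires 'counts'", call. = FALSE)
    counts <- as.integer(counts)
    if (length(counts) != k || sum(counts) != n_total) {
      stop("'counts' must have one entry per class and sum to n_total",
           call. = FALSE)
    }
  }
  structure(list(priors = priors, means = means, sds = sds,
                 n_total = n_total, mode = mode, counts = counts),
            class = "gmm_spec")
}

#' Canonical three-class univariate mixture specification
#'
#' The introductory benchmark mixture: priors `[0.6, 0.1, 0.3]`, means
#' `[0, 4, 6]`, standard deviations `[2, 0.001, 0.2]`, 3000 instances,
#' priors mode. The middle class is tiny and extremely narrow, which is
#' what makes it a good probe for whether small (or hidden) classes survive
#' downsampling.
#'
#' @return A [gmm_spec()].
#' @export
default_gmm1d_spec <- function() {
  gmm_spec(priors = c(0.6, 0.1, 0.3), means = c(0, 4, 6),
           sds = c(2, 0.001, 0.2), n_total = 3000L)
}

#' Generate a univariate Gaussian-mixture data table
#'
#' @param spec a [gmm_spec()].
#' @param seed integer seed; the draw is fully reproducible.
#' @return A [data_table()] with one numeric column `x` and integer class
#'   labels `1..k`.
#' @examples
#' dt <- generate_gmm1d(default_gmm1d_spec(), seed = 1)
#' table(dt$labels)
#' @export
generate_gmm1d <- function(spec, seed) {
  stopifnot(inherits(spec, "gmm_spec"))
  k <- length(spec$priors)
  withr::with_seed(as.integer(seed), {
    cls <- if (spec$mode == "fixed") {
      rep.int(seq_len(k), spec$counts)
    } else {
      sample.int(k, spec$n_total, replace = TRUE, prob = spec$priors)
    }
    x <- stats::rnorm(spec$n_total, mean = spec$means[cls],
                      sd = spec$sds[cls])
    data_table(matrix(x, ncol = 1L, dimnames = list(NULL, "x")),
               labels = cls)
  })
}

#' Generate a multivariate three-modal Gaussian data table
#'
#' Ten-variable (by default) benchmark with a clear three-group structure:
#' instances belong to three classes with priors `[0.5, 0.4, 0.1]`; each
#' variable independently receives three Gaussian components whose means
#' are drawn uniformly from `mean_range` and standard deviations from
#' `sd_range`, with component means sorted ascending so that class 1 holds
#' the smallest component mean of every variable (group numbers in
#' ascending order of the means).
#'
#' @param n number of instances (default 30000).
#' @param p number of variables (default 10).
#' @param priors class prior weights (default `c(0.5, 0.4, 0.1)`).
#' @param mean_range,sd_range uniform ranges for the component means
#'   (default `[1, 100]`) and standard deviations (default `[1, 30]`).
#' @param seed integer seed.
#' @return A [data_table()] with `p` columns `V1..Vp` and integer labels.
#' @export
generate_gmm_multivar <- function(n = 30000L, p = 10L,
                                  priors = c(0.5, 0.4, 0.1),
                                  mean_range = c(1, 100), sd_range = c(1, 30),
                                  seed) {
  n <- as.integer(n)
  p <- as.integer(p)
  if (n < 1L || p < 1L) stop("'n' and 'p' must be positive", call. = FALSE)
  if (mean_range[1] > mean_range[2] || sd_range[1] > sd_range[2] ||
      sd_range[1] <= 0) {
    stop("invalid 'mean_range' or 'sd_range'", call. = FALSE)
  }
  k <- length(priors)
  withr::with_seed(as.integer(seed), {
    cls <- sample.int(k, n, replace = TRUE, prob = priors)
    X <- matrix(0, nrow = n, ncol = p,
                dimnames = list(NULL, paste0("V", seq_len(p))))
    for (j in seq_len(p)) {
      mu <- stats::runif(k, mean_range[1], mean_range[2])
      sd <- stats::runif(k, sd_range[1], sd_range[2])
      o <- order(mu)
      mu <- mu[o]
      sd <- sd[o]
      X[, j] <- stats::rnorm(n, mean = mu[cls], sd = sd[cls])
    }
    data_table(X, labels = cls)
  })
}

#' Append outliers to a univariate table
#'
#' Builds the outlier stress scenario: a run of values far outside the
#' base data's range is appended to a one-column table. With
#' `outlier_class` given, the outliers form their own class (and the base
#' rows keep their labels, or get class `1` if unlabelled); without it, all
#' class information is dropped and every row -- base and outlier alike --
#' belongs to a single class, emulating downsampling when no prior class
#' knowledge exists.
#'
#' @param base a one-column [data_table()].
#' @param outlier_values numeric vector of outliers to append; the default
#'   is the ten consecutive integers `15..24`.
#' @param outlier_class label for the outlier rows, or `NULL` to drop all
#'   class information.
#' @return A [data_table()] with `nrow(base) + length(outlier_values)` rows.
#' @export
make_outlier_scenario <- function(base, outlier_values = 15:24,
                                  outlier_class = NULL) {
  stopifnot(inherits(base, "data_table"))
  if (ncol(base$values) != 1L) {
    stop("'base' must have exactly one column", call. = FALSE)
  }
  if (length(outlier_values) < 1L) stop("no outlier values", call. = FALSE)
  vals <- matrix(c(base$values[, 1L], outlier_values), ncol = 1L,
                 dimnames = list(NULL, colnames(base$values)))
  n_out <- length(outlier_values)
  labels <- if (is.null(outlier_class)) {
    rep.int(1L, nrow(vals))
  } else {
    base_labels <- if (is.null(base$labels)) rep.int(1L, nrow(base$values))
                   else base$labels
    c(base_labels, rep(outlier_class, n_out))
  }
  data_table(vals, labels = labels, label_name = base$label_name)
}
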