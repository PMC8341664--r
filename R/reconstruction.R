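#' Fit a PCA model on a sample
#'
#' Centered, unscaled principal component analysis of the sample's values,
#' retaining the components whose covariance eigenvalues exceed 1
#' (Kaiser-Guttman criterion). Because the data are not rescaled, the
#' eigenvalue threshold is deliberately scale-dependent. When no eigenvalue
#' exceeds 1 the first component is retained as a fallback (an empty
#' projection would be undefined); a message notes the fallback.
#'
#' @param sample a [data_table()] or numeric matrix with at least 2 rows.
#' @return An object of class `pca_model`: `center` (length-p mean vector),
#'   `loadings` (p x k orthonormal columns), `eigenvalues` (descending,
#'   length k) and `k`.
#' @examples
#' m <- fit_pca(matrix(rnorm(100, sd = 3), ncol = 2))
#' crossprod(m$loadings)  # identity
#' @export
fit_pca <- function(sample) {
  X <- if (inherits(sample, "data_table")) sample$values else as.matrix(sample)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit a PCA", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- sum(ev > 1)
  if (k == 0L) {
    message("no covariance eigenvalue exceeds 1; retaining the first ",
            "component")
    k <- 1L
  }
  structure(
    list(center = pc$center,
         loadings = pc$rotation[, seq_len(k), drop = FALSE],
         eigenvalues = ev[seq_len(k)],
         k = k),
    class = "pca_model"
  )
}

#' Reconstruct rows through a PCA model
#'
#' Projects held-out rows onto the model's principal subspace and maps them
#' back: `scores = (X - center) %*% loadings`,
#' `X_reco = scores %*% t(loadings) + center`. This is an orthogonal
#' projection (plus the centering shift), hence idempotent, and exact for
#' rows lying in the retained affine subspace.
#'
#' @param model a [fit_pca()] model.
#' @param x_remaining a [data_table()] or numeric matrix with the model's
#'   number of columns.
#' @return Numeric matrix of reconstructed rows, same shape as the input.
#' @export
reconstruct <- function(model, x_remaining) {
  stopifnot(inherits(model, "pca_model"))
  X <- if (inherits(x_remaining, "data_table")) x_remaining$values
       else as.matrix(x_remaining)
  if (ncol(X) != nrow(model$loadings)) {
    stop("dimension mismatch: model expects p = ", nrow(model$loadings),
         " columns", call. = FALSE)
  }
  centered <- sweep(X, 2L, model$center)
  scores <- centered %*% model$loadings
  sweep(scores %*% t(model$loadings), 2L, model$center, "+")
}

#' Mean squared reconstruction error
#'
#' `MSE = sum_ij (X_reco[i,j] - X_remaining[i,j])^2 / (n p)`: the mean of
#' squared elementwise differences over all cells, with `n` the number of
#' unselected instances and `p` the number of features.
#'
#' @param x_reco,x_remaining numeric matrices of identical shape, at least
#'   one row.
#' @return A single non-negative number.
#' @examples
#' reconstruction_mse(rbind(3, 2), rbind(1, 2))  # 2
#' @export
reconstruction_mse <- function(x_reco, x_remaining) {
  x_reco <- as.matrix(x_reco)
  x_remaining <- as.matrix(x_remaining)
  if (!identical(dim(x_reco), dim(x_remaining))) {
    stop("shape mismatch", call. = FALSE)
  }
  if (nrow(x_reco) < 1L) stop("empty remaining set", call. = FALSE)
  mean((x_reco - x_remaining)^2)
}

#' Downsampling quality over a fraction-by-trials experiment grid
#'
#' For every combination of sampled fraction, trial count and replicate:
#' runs [dp_downsample()], fits a PCA on the winning sample, reconstructs
#' the removed remainder and records the mean squared reconstruction error.
#' Replicates start at disjoint seed blocks
#' (`base_seed + (replicate - 1) * max(n_trials_list)`), so no trial seed
#' is reused across replicates, and within a replicate the single-trial run
#' is exactly the first trial of the longer runs (paired by construction).
#'
#' @param data a [data_table()].
#' @param fractions numeric vector of sampled fractions in (0, 1); the
#'   retained size is `max(1, round(fraction * n))`.
#' @param n_trials_list integer vector of trial counts.
#' @param n_replicates number of replicates (default 20).
#' @param metric_id distance token (default `"ad"`).
#' @param base_seed integer base seed for the first replicate.
#' @param max_workers,job_size passed to [run_config()].
#' @return A data frame with one row per (fraction, n_trials, replicate):
#'   columns `fraction`, `n_trials`, `replicate`, `seed`, `metric`,
#'   `k_components`, `mse`.
#' @export
evaluate_downsampling <- function(data, fractions, n_trials_list,
                                  n_replicates = 20L, metric_id = "ad",
                                  base_seed = 0L, max_workers = 1L,
                                  job_size = 10000L) {
  stopifnot(inherits(data, "data_table"))
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("fractions must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(data$values)
  sizes <- pmax(1L, as.integer(round(fractions * n)))
  if (any(sizes >= n)) stop("fraction too large for this data", call. = FALSE)
  n_trials_max <- max(n_trials_list)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      fraction_i = seq_along(fractions),
                      n_trials = sort(unique(as.integer(n_trials_list))))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rep_i <- grid$replicate[i]
    fr_i <- grid$fraction_i[i]
    nt <- grid$n_trials[i]
    seed <- base_seed + (rep_i - 1L) * n_trials_max
    cfg <- run_config(size = sizes[fr_i], seed = seed, n_trials = nt,
                      metric_id = metric_id, max_workers = max_workers,
                      job_size = job_size)
    res <- dp_downsample(data, cfg)
    model <- suppressMessages(fit_pca(res$sample))
    mse <- reconstruction_mse(reconstruct(model, res$removed),
                              res$removed$values)
    data.frame(fraction = fractions[fr_i], n_trials = nt, replicate = rep_i,
               seed = seed, metric = cfg$metric_id, k_components = model$k,
               mse = mse)
  })
  do.call(rbind, rows)
}
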