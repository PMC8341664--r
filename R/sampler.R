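#' Run configuration for distribution-preserving downsampling
#'
#' Bundles the tunable parameters of [dp_downsample()]. Defaults follow the
#' method's published parameterisation: 1000 trials, Anderson-Darling
#' distance, up to 8 workers, chunks of 10000 trials, importance filtering
#' off.
#'
#' @param size number of instances to retain; must be positive and smaller
#'   than the number of rows of the target data.
#' @param seed integer base seed. Trial `t` uses seed `seed + t`, so the
#'   canonical scheme enumerates seeds `1..n_trials` when `seed = 0`, and
#'   disjoint base seeds combine independent runs into one larger search.
#' @param n_trials number of seeded sampling trials (default 1000).
#' @param metric_id distance token, one of [metric_ids()] (default `"ad"`).
#' @param max_workers upper bound on parallel workers (default 8); results
#'   are independent of the worker count.
#' @param job_size number of trials per sequentially merged chunk
#'   (default 10000); bounds memory, never changes the result.
#' @param pca_importance if `TRUE`, distances are assessed only over the
#'   variables retained by [select_relevant_features_pca()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(size, seed = 0L, n_trials = 1000L, metric_id = "ad",
                       max_workers = 8L, job_size = 10000L,
                       pca_importance = FALSE) {
  size <- as.integer(size)
  n_trials <- as.integer(n_trials)
  job_size <- as.integer(job_size)
  max_workers <- as.integer(max_workers)
  seed <- as.integer(seed)
  if (is.na(size) || size < 1L) stop("'size' must be a positive integer",
                                     call. = FALSE)
  if (is.na(n_trials) || n_trials < 1L) stop("'n_trials' must be >= 1",
                                             call. = FALSE)
  if (is.na(job_size) || job_size < 1L) stop("'job_size' must be >= 1",
                                             call. = FALSE)
  if (is.na(max_workers) || max_workers < 1L) stop("'max_workers' must be >= 1",
                                                   call. = FALSE)
  structure(
    list(size = size, seed = seed, n_trials = n_trials,
         metric_id = .match_metric(metric_id), max_workers = max_workers,
         job_size = job_size, pca_importance = isTRUE(pca_importance)),
    class = "run_config"
  )
}

# Largest-remainder apportionment of `size` over classes with the given
# counts: floors of the exact quotas, then the remaining units to the
# largest fractional remainders (ties broken by class order). Guarantees
# the quotas sum to `size` exactly; a small class may legitimately get 0.
.class_quotas <- function(counts, size) {
  q <- size * counts / sum(counts)
  base <- floor(q)
  rem <- size - sum(base)
  if (rem > 0) {
    o <- order(-(q - base), seq_along(q))
    top <- o[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# Uniform within-class draw given precomputed class index lists.
.draw_stratified <- function(groups, quotas, seed) {
  idx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(groups), function(g) {
      k <- quotas[g]
      if (k == 0L) integer(0) else groups[[g]][sample.int(length(groups[[g]]), k)]
    }), use.names = FALSE)
  })
  sort.int(idx)
}

#' Seeded class-proportional uniform sample indices
#'
#' Draws `size` row indices so that each class receives its
#' largest-remainder share of `size` (preserving the class priors up to
#' per-class rounding) and, within each class, every instance has equal
#' inclusion probability. The draw is fully determined by `seed`.
#'
#' @param labels class label per row; a single repeated value (or a
#'   length-one class set) reduces to plain uniform sampling.
#' @param size number of indices to draw, `1 <= size < length(labels)`.
#' @param seed integer seed for this draw.
#' @return Sorted integer vector of `size` distinct 1-based row indices.
#' @examples
#' stratified_sample_indices(rep(c("a", "b", "c"), c(60, 10, 30)), 10, 1)
#' @export
stratified_sample_indices <- function(labels, size, seed) {
  n <- length(labels)
  if (n < 1L) stop("empty labels", call. = FALSE)
  size <- as.integer(size)
  if (size < 1L || size >= n) {
    stop("'size' must satisfy 1 <= size < n", call. = FALSE)
  }
  classes <- unique(labels)
  groups <- lapply(classes, function(cl) which(labels == cl))
  quotas <- .class_quotas(lengths(groups), size)
  .draw_stratified(groups, quotas, seed)
}

# Precompute, per assessed variable, whatever the metric needs against the
# full column: sorted values for ECDF metrics, grid + full density for PDF
# metrics. Constant columns are flagged (distance 0 by convention).
.distance_context <- function(values, metric, variables) {
  cols <- lapply(variables, function(v) {
    fc <- values[, v]
    const <- min(fc) == max(fc)
    out <- list(constant = const)
    if (!const) {
      if (metric %in% .ecdf_metrics) {
        out$sorted <- sort.int(fc, method = "quick")
      } else {
        out$grid <- make_grid(fc)
        out$full_pdf <- estimate_pdf(fc, out$grid)
      }
    }
    out
  })
  names(cols) <- variables
  list(metric = metric, variables = variables,
       raw = values[, variables, drop = FALSE], cols = cols,
       core = if (metric %in% .ecdf_metrics) .ecdf_cores[[metric]] else NULL)
}

.trial_distances <- function(idx, ctx) {
  vapply(ctx$variables, function(v) {
    col <- ctx$cols[[v]]
    if (col$constant) return(0)
    sv <- ctx$raw[idx, v]
    if (!is.null(ctx$core)) {
      po <- .pooled_merge(sort.int(sv, method = "quick"), col$sorted)
      ctx$core(po$z, po$isx, length(sv), length(col$sorted))
    } else {
      p <- estimate_pdf(sv, col$grid)
      switch(ctx$metric,
             kld = kld_sym_dist(p, col$full_pdf),
             euc = euclidean_pdf_dist(p, col$full_pdf),
             amrdd = amrdd_dist(p, col$full_pdf))
    }
  }, numeric(1))
}

#' Run a single seeded sampling trial
#'
#' Trial `t` of a run draws a class-proportional sample with seed
#' `config$seed + t` and computes, for every assessed variable, the
#' distance between the sample's distribution and the full data's.
#'
#' @param data a [data_table()].
#' @param config a [run_config()]; `trial_index` must lie in
#'   `1..config$n_trials`.
#' @param trial_index which trial to run.
#' @param variables character vector of feature names to assess (default:
#'   all features).
#' @return An object of class `trial_result`: `trial_seed`,
#'   `selected_indices` (sorted, 1-based), `per_variable_distance` (named)
#'   and `max_distance`.
#' @export
run_trial <- function(data, config, trial_index, variables = NULL) {
  stopifnot(inherits(data, "data_table"), inherits(config, "run_config"))
  trial_index <- as.integer(trial_index)
  if (trial_index < 1L || trial_index > config$n_trials) {
    stop("'trial_index' must lie in 1..n_trials", call. = FALSE)
  }
  if (is.null(variables)) variables <- data$feature_names
  n <- nrow(data$values)
  if (config$size >= n) stop("'size' must be smaller than n", call. = FALSE)
  labels <- if (is.null(data$labels)) rep.int(1L, n) else data$labels
  ctx <- .distance_context(data$values, config$metric_id, variables)
  classes <- unique(labels)
  groups <- lapply(classes, function(cl) which(labels == cl))
  quotas <- .class_quotas(lengths(groups), config$size)
  .one_trial(trial_index, config$seed, groups, quotas, ctx)
}

.one_trial <- function(trial_index, base_seed, groups, quotas, ctx) {
  seed <- base_seed + trial_index
  idx <- .draw_stratified(groups, quotas, seed)
  d <- .trial_distances(idx, ctx)
  structure(
    list(trial_seed = seed, selected_indices = idx,
         per_variable_distance = d, max_distance = max(d)),
    class = "trial_result"
  )
}

# Runs one chunk of trial indices and returns the chunk's best trial plus
# the vector of max-distances (diagnostics). The best is the strict argmin
# scanning seeds in ascending order, so ties resolve to the lowest seed.
.chunk_run <- function(trial_indices, base_seed, groups, quotas, ctx) {
  best <- NULL
  maxs <- numeric(length(trial_indices))
  for (i in seq_along(trial_indices)) {
    tr <- .one_trial(trial_indices[i], base_seed, groups, quotas, ctx)
    maxs[i] <- tr$max_distance
    if (is.null(best) || tr$max_distance < best$max_distance) best <- tr
  }
  list(best = best, maxs = maxs)
}

#' Optimal distribution-preserving downsampling
#'
#' The core algorithm: repeats seeded class-proportional uniform sampling
#' `n_trials` times, scores every trial by the maximum over variables of
#' the distance between the sample's distribution and the full data's, and
#' returns the trial minimising that maximum (ties broken by the lowest
#' trial seed). Trials are processed in chunks of `job_size`, optionally in
#' parallel; because each trial is fully determined by its own seed and the
#' chunk merge is an associative argmin, the result is independent of
#' chunking and worker count.
#'
#' @param data a [data_table()]; unlabelled data is treated as one class.
#' @param config a [run_config()] with `size < nrow(data$values)`.
#' @return An object of class `sampling_result`: `winner` (the best
#'   `trial_result`), `sample` and `removed` ([data_table()]s partitioning
#'   the input), `config`, `n_trials_run`, `variables_assessed`, and
#'   `trial_max_distances` (per-trial max distance, in trial order).
#' @examples
#' dt <- data_table(matrix(rnorm(200), ncol = 2),
#'                  labels = rep(c(1, 2), each = 50))
#' res <- dp_downsample(dt, run_config(size = 10, seed = 0, n_trials = 50))
#' res$winner$max_distance
#' @export
dp_downsample <- function(data, config) {
  stopifnot(inherits(data, "data_table"), inherits(config, "run_config"))
  n <- nrow(data$values)
  if (config$size >= n) {
    stop("'size' (", config$size, ") must be smaller than n (", n, ")",
         call. = FALSE)
  }
  variables <- data$feature_names
  if (config$pca_importance && ncol(data$values) >= 2L) {
    variables <- select_relevant_features_pca(data)
    if (length(variables) < 1L) {
      warning("PCA importance filtering selected no variables; ",
              "falling back to all variables", call. = FALSE)
      variables <- data$feature_names
    }
  }
  labels <- if (is.null(data$labels)) rep.int(1L, n) else data$labels
  classes <- unique(labels)
  groups <- lapply(classes, function(cl) which(labels == cl))
  quotas <- .class_quotas(lengths(groups), config$size)
  ctx <- .distance_context(data$values, config$metric_id, variables)

  chunks <- split(seq_len(config$n_trials),
                  ceiling(seq_len(config$n_trials) / config$job_size))
  workers <- min(config$max_workers, parallel::detectCores())
  run_one <- function(tri) .chunk_run(tri, config$seed, groups, quotas, ctx)
  chunk_res <- if (workers > 1L && length(chunks) > 1L &&
                   .Platform$OS.type == "unix") {
    parallel::mclapply(chunks, run_one, mc.cores = workers)
  } else {
    lapply(chunks, run_one)
  }

  best <- NULL
  for (cr in chunk_res) {
    if (is.null(best) || cr$best$max_distance < best$max_distance ||
        (cr$best$max_distance == best$max_distance &&
         cr$best$trial_seed < best$trial_seed)) {
      best <- cr$best
    }
  }
  idx <- best$selected_indices
  structure(
    list(winner = best,
         sample = dt_rows(data, idx),
         removed = dt_rows(data, setdiff(seq_len(n), idx)),
         config = config,
         n_trials_run = config$n_trials,
         variables_assessed = variables,
         trial_max_distances = unlist(lapply(chunk_res, `[[`, "maxs"),
                                      use.names = FALSE)),
    class = "sampling_result"
  )
}

#' @export
print.sampling_result <- function(x, ...) {
  cat(sprintf(paste0("<sampling_result: %d of %d rows retained, metric '%s',",
                     " %d trials,\n  winning seed %d, max distance %.6g>\n"),
              nrow(x$sample$values),
              nrow(x$sample$values) + nrow(x$removed$values),
              x$config$metric_id, x$n_trials_run, x$winner$trial_seed,
              x$winner$max_distance))
  invisible(x)
}

#' PCA-based selection of relevant variables
#'
#' Screens variables before distance assessment so the subset search does
#' not optimise for irrelevant ones. A centered, unscaled principal
#' component analysis of the full data is computed; components with
#' covariance eigenvalue above 1 are retained (Kaiser-Guttman criterion); a
#' variable is relevant if its contribution to at least one retained
#' component -- `100 * loading^2 / sum(loadings^2)` on that component --
#' exceeds the uniform expectation `100 / p`.
#'
#' @param data a [data_table()] with at least 2 variables.
#' @return Character vector of relevant feature names in original column
#'   order; may be empty when no component passes the eigenvalue criterion.
#'   All-constant data triggers a warning and returns all features.
#' @export
select_relevant_features_pca <- function(data) {
  stopifnot(inherits(data, "data_table"))
  X <- data$values
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 variables", call. = FALSE)
  rng <- apply(X, 2L, function(cc) max(cc) - min(cc))
  if (all(rng == 0)) {
    warning("degenerate (all-constant) data; returning all variables",
            call. = FALSE)
    return(data$feature_names)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(ev > 1)
  if (length(keep) == 0L) return(character(0))
  contrib <- sweep(pc$rotation[, keep, drop = FALSE]^2, 2L,
                   colSums(pc$rotation[, keep, drop = FALSE]^2), "/") * 100
  relevant <- rowSums(contrib > 100 / p) > 0
  data$feature_names[relevant]
}
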