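# Shared fixtures, built in code.

# Two classes of four rows each, two variables; the size-4 class-
# proportional sampling space has exactly choose(4,2)^2 = 36 subsets.
tiny_two_class <- function() {
  vals <- cbind(a = c(0.3, 1.2, 2.7, 3.9, 10.1, 11.8, 13.2, 14.9),
                b = c(5.0, 4.1, 6.3, 5.6, -2.0, -1.1, -3.4, -2.6))
  data_table(vals, labels = rep(c("A", "B"), each = 4))
}

# All class-proportional index sets of size 4 (2 per class) for the tiny
# fixture, as a list of sorted index vectors.
tiny_all_subsets <- function() {
  pairs1 <- utils::combn(1:4, 2, simplify = FALSE)
  pairs2 <- utils::combn(5:8, 2, simplify = FALSE)
  out <- list()
  for (p1 in pairs1) for (p2 in pairs2) out[[length(out) + 1]] <- c(p1, p2)
  out
}

# Brute-force min-max winner over an explicit subset list.
brute_force_minmax <- function(dt, subsets, metric) {
  best <- Inf
  for (idx in subsets) {
    d <- vapply(dt$feature_names, function(v) {
      compare_distributions(dt$values[idx, v], dt$values[, v], metric)
    }, numeric(1))
    best <- min(best, max(d))
  }
  best
}

# The classic 150 x 4 three-class iris table as a data_table.
iris_table <- function() {
  data_table(as.matrix(datasets::iris[, 1:4]),
             labels = as.character(datasets::iris$Species),
             label_name = "Species")
}
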