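#' Numeric data table with optional class labels
#'
#' The central container of the package: an `n x p` numeric matrix of
#' instances (rows) by variables (columns), optionally accompanied by a
#' per-row class label used for class-proportional sampling. Missing values
#' are rejected outright -- imputation would alter the very distributions the
#' downsampling method is designed to preserve.
#'
#' @param values numeric matrix or data frame coercible to one; `n >= 1`
#'   rows and `p >= 1` columns, no `NA`/`NaN` entries.
#' @param labels optional vector of class identifiers, length `n`, with at
#'   least one distinct value. `NULL` means unlabelled data (treated as a
#'   single class by the sampler).
#' @param feature_names optional character vector of length `p`; defaults to
#'   the column names of `values` or `V1..Vp`.
#' @param row_ids optional vector of stable row identifiers of length `n`;
#'   defaults to the 0-based original row index, which is what selection
#'   reports refer to.
#' @param label_name name under which the label column is written back to
#'   disk (default `"cls"`).
#'
#' @return An object of class `data_table` with elements `values`, `labels`,
#'   `feature_names`, `row_ids`, `label_name`.
#' @examples
#' dt <- data_table(cbind(x = 1:4, y = c(2, 2, 3, 3)), labels = c(1, 1, 2, 2))
#' dt$values
#' @export
data_table <- function(values, labels = NULL, feature_names = NULL,
                       row_ids = NULL, label_name = "cls") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (n < 1L || p < 1L) {
    stop("'values' must have at least one row and one column", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing value or non-finite entry in 'values'", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))
  }
  if (length(feature_names) != p) {
    stop("'feature_names' must have length p = ", p, call. = FALSE)
  }
  colnames(values) <- feature_names
  if (!is.null(labels)) {
    if (is.factor(labels)) labels <- as.character(labels)
    if (length(labels) != n) {
      stop("'labels' must have length n = ", n, call. = FALSE)
    }
    if (anyNA(labels)) stop("missing value in 'labels'", call. = FALSE)
    if (length(unique(labels)) < 1L) {
      stop("'labels' must contain at least one distinct value", call. = FALSE)
    }
  }
  if (is.null(row_ids)) row_ids <- seq_len(n) - 1L
  if (length(row_ids) != n) {
    stop("'row_ids' must have length n = ", n, call. = FALSE)
  }
  structure(
    list(values = values, labels = labels, feature_names = feature_names,
         row_ids = row_ids, label_name = label_name),
    class = "data_table"
  )
}

#' @export
print.data_table <- function(x, ...) {
  cat(sprintf("<data_table: %d instances x %d variables%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) ", unlabelled"
              else sprintf(", %d classes", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.data_table <- function(x) dim(x$values)

#' Subset the rows of a data table
#'
#' @param data a [data_table()].
#' @param idx integer row indices (1-based).
#' @return A `data_table` holding the selected rows; `row_ids` (and labels)
#'   travel with the rows.
#' @keywords internal
#' @export
dt_rows <- function(data, idx) {
  data_table(data$values[idx, , drop = FALSE],
             labels = if (is.null(data$labels)) NULL else data$labels[idx],
             feature_names = data$feature_names,
             row_ids = data$row_ids[idx],
             label_name = data$label_name)
}

#' Read a numeric table from CSV/TSV
#'
#' Reads a delimited text file with a header row into a [data_table()].
#' The delimiter is sniffed from the header line (tab if present, otherwise
#' comma). All value columns must parse as numbers; any missing value is an
#' error.
#'
#' @param path path to an existing CSV or TSV file.
#' @param label_column name of the class-label column, or `NULL` for
#'   unlabelled data. When given, the column is removed from the numeric
#'   values and stored as labels.
#' @return A [data_table()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(a = 1:3, b = 4:6, cls = c("u", "u", "v")), f,
#'           row.names = FALSE)
#' read_table(f, label_column = "cls")
#' @export
read_table <- function(path, label_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"")
  if (nrow(df) < 1L) stop("empty table: ", path, call. = FALSE)
  labels <- NULL
  label_name <- "cls"
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not found in ", path,
           call. = FALSE)
    }
    labels <- df[[label_column]]
    label_name <- label_column
    df[[label_column]] <- NULL
    if (ncol(df) < 1L) stop("no value columns besides the label column",
                            call. = FALSE)
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric cell in value column(s): ",
         paste(names(df)[bad], collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df)
  if (anyNA(vals)) stop("missing value in ", path, call. = FALSE)
  data_table(vals, labels = labels, label_name = label_name)
}

# Full round-trip precision for doubles.
.fmt_num <- function(x) sprintf("%.17g", x)

.write_dt_csv <- function(dt, path) {
  vals <- dt$values
  out <- matrix(.fmt_num(vals), nrow = nrow(vals))
  colnames(out) <- dt$feature_names
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  quote_cols <- integer(0)
  if (!is.null(dt$labels)) {
    df[[dt$label_name]] <- as.character(dt$labels)
    quote_cols <- ncol(df)
  }
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = quote_cols, qmethod = "double")
  invisible(path)
}

#' Write a sampling result to disk
#'
#' Writes three files: `<prefix>.sample.csv` (the retained rows),
#' `<prefix>.removed.csv` (all other rows) and `<prefix>.report.json`
#' (winning trial seed, metric, per-variable distances and their maximum,
#' plus the 0-based row ids of the retained rows). Together the two CSV
#' files partition the original table exactly. Numeric cells are written at
#' 17 significant digits so a read-back round-trips bit-exactly.
#'
#' @param result a `sampling_result` as returned by [dp_downsample()].
#' @param out_prefix path prefix for the three output files.
#' @return Invisibly, a character vector of the three paths written.
#' @export
write_result <- function(result, out_prefix) {
  stopifnot(inherits(result, "sampling_result"))
  if (nrow(result$removed$values) < 1L) {
    stop("removed set is empty; 'size' must be smaller than n", call. = FALSE)
  }
  paths <- paste0(out_prefix, c(".sample.csv", ".removed.csv", ".report.json"))
  .write_dt_csv(result$sample, paths[1L])
  .write_dt_csv(result$removed, paths[2L])
  report <- list(
    winning_seed = result$winner$trial_seed,
    metric = result$config$metric_id,
    size = result$config$size,
    n_trials = result$n_trials_run,
    per_variable_distance = as.list(result$winner$per_variable_distance),
    max_distance = result$winner$max_distance,
    variables_assessed = result$variables_assessed,
    selected_row_ids = result$sample$row_ids
  )
  jsonlite::write_json(report, paths[3L], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
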