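#' Samples-by-features tables
#'
#' The basic data container: a numeric matrix of tissue samples (rows) by
#' cell-level features (columns). Columns are either `continuous`
#' (prevalence or state scores, non-negative) or `attribute01` (binary
#' sample attributes such as "Cancer", coded 0/1).
#'
#' @param values numeric matrix or data.frame, samples x features.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to rownames or `sample_1..n`.
#' @param column_kind named character vector mapping features to
#'   `"continuous"` or `"attribute01"`. Unspecified columns default to
#'   `continuous`; binary sample attributes must be declared explicitly.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, sample_ids = NULL, column_kind = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    stop("feature columns must be named")
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match the number of rows")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing value at sample '", sample_ids[bad[1]], "', feature '",
         colnames(values)[bad[2]], "'; missing entries are not allowed")
  }
  kind <- rep("continuous", ncol(values))
  names(kind) <- colnames(values)
  if (!is.null(column_kind)) {
    unknown <- setdiff(names(column_kind), colnames(values))
    if (length(unknown) > 0)
      stop("column_kind names unknown feature(s): ",
           paste(unknown, collapse = ", "))
    bad_kind <- setdiff(column_kind, c("continuous", "attribute01"))
    if (length(bad_kind) > 0)
      stop("column_kind must be 'continuous' or 'attribute01'")
    kind[names(column_kind)] <- column_kind
  }
  for (f in names(kind)[kind == "attribute01"]) {
    if (!all(values[, f] %in% c(0, 1)))
      stop("attribute01 column '", f, "' contains values outside {0, 1}")
  }
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 feature_names = colnames(values), column_kind = kind,
                 normalized = FALSE),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "samples x", ncol(x$values),
      "features (", sum(x$column_kind == "attribute01"), "attribute,",
      sum(x$column_kind == "continuous"), "continuous )\n")
  if (isTRUE(x$normalized)) cat("  normalized to [0, 1]\n")
  invisible(x)
}

# numeric matrix from a feature_table or matrix-like input
as_feature_matrix <- function(data) {
  if (inherits(data, "feature_table")) return(data$values)
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  m
}

#' Macrophage functional-orientation probabilities
#'
#' Collapses the three macrophage prevalence scores (M0, M1, M2 subtypes)
#' into the probability of the average functional orientation:
#' `p(Mi) = Mi / (M0 + M1 + M2)`. Samples with all three scores zero carry
#' no orientation information; they are returned as `NA` with a warning and
#' flagged in the `degenerate` attribute.
#'
#' @param m0,m1,m2 non-negative numeric vectors of equal length.
#' @return a data.frame with columns `p_m0`, `p_m1`, `p_m2` and a logical
#'   attribute `degenerate` marking all-zero samples.
#' @examples
#' macrophage_orientation(1, 1, 2)  # 0.25, 0.25, 0.5
#' @export
macrophage_orientation <- function(m0, m1, m2) {
  if (length(m1) != length(m0) || length(m2) != length(m0))
    stop("m0, m1, m2 must have equal length")
  if (any(m0 < 0 | m1 < 0 | m2 < 0, na.rm = TRUE))
    stop("macrophage prevalence scores must be non-negative")
  tot <- m0 + m1 + m2
  degenerate <- tot == 0
  tot[degenerate] <- NA_real_
  out <- data.frame(p_m0 = m0 / tot, p_m1 = m1 / tot, p_m2 = m2 / tot)
  if (any(degenerate))
    warning(sum(degenerate), " sample(s) with zero total macrophage ",
            "content; orientation probabilities set to NA")
  attr(out, "degenerate") <- degenerate
  out
}

#' Preprocessing configuration
#'
#' @param log_offset positive offset added before the log transform
#'   (default 1: zero scores stay at zero).
#' @param log_base base of the logarithm (default 10).
#' @param n_intervals number of equal-width discretization intervals, or
#'   `NULL` for no discretization. The reference analyses used 15 intervals
#'   for the large breast-cancer cohort and 6 for the smaller melanoma
#'   cohorts.
#' @param discretize logical; discretize after normalization?
#' @param zero_leaf_fraction features whose fraction of exact zeros reaches
#'   this threshold are suggested as leaf nodes (default 0.5).
#' @export
preprocess_config <- function(log_offset = 1, log_base = 10,
                              n_intervals = NULL, discretize = FALSE,
                              zero_leaf_fraction = 0.5) {
  if (log_offset <= 0) stop("log_offset must be positive")
  if (discretize && (is.null(n_intervals) || n_intervals < 2))
    stop("discretization requires n_intervals >= 2")
  if (zero_leaf_fraction <= 0 || zero_leaf_fraction > 1)
    stop("zero_leaf_fraction must be in (0, 1]")
  structure(list(log_offset = log_offset, log_base = log_base,
                 n_intervals = n_intervals, discretize = discretize,
                 zero_leaf_fraction = zero_leaf_fraction),
            class = "preprocess_config")
}

#' Log-transform and normalize continuous features to [0, 1]
#'
#' Each continuous column is mapped `x -> log(x + log_offset)` and then
#' min-max scaled so the column minimum is 0 and the maximum is 1.
#' Attribute columns pass through unchanged. Constant columns carry no
#' information for network learning; they are mapped to all-zero with a
#' warning. The transform is applied exactly once: the returned table is
#' flagged `normalized` and re-normalizing it is an error.
#'
#' @param table a [feature_table()].
#' @param cfg a [preprocess_config()].
#' @return a normalized `feature_table`.
#' @export
preprocess_features <- function(table, cfg = preprocess_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (isTRUE(table$normalized))
    stop("table is already normalized; preprocess_features() must be ",
         "applied exactly once")
  vals <- table$values
  for (f in table$feature_names) {
    if (table$column_kind[[f]] != "continuous") next
    x <- vals[, f]
    if (any(x < 0))
      stop("continuous feature '", f, "' has negative values; ",
           "prevalence scores must be non-negative")
    x <- log(x + cfg$log_offset, base = cfg$log_base)
    rng <- range(x)
    if (rng[1] == rng[2]) {
      warning("feature '", f, "' is constant; normalized to all zeros")
      vals[, f] <- 0
    } else {
      vals[, f] <- (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  out <- table
  out$values <- vals
  out$normalized <- TRUE
  out
}

#' Discretize a normalized table into equal-width intervals
#'
#' Bins values in \[0, 1\] into `n_intervals` equal-width intervals coded
#' `0 .. n_intervals - 1`; the value 1.0 falls in the top interval.
#' Attribute columns pass through unchanged.
#'
#' @param table a normalized [feature_table()].
#' @param n_intervals integer >= 2.
#' @return a `feature_table` with integer-coded continuous columns.
#' @export
discretize_features <- function(table, n_intervals) {
  stopifnot(inherits(table, "feature_table"))
  if (n_intervals < 2) stop("n_intervals must be >= 2")
  if (!isTRUE(table$normalized))
    stop("discretize_features() expects a normalized table")
  vals <- table$values
  cont <- table$feature_names[table$column_kind == "continuous"]
  for (f in cont) {
    codes <- floor(vals[, f] * n_intervals)
    codes[codes >= n_intervals] <- n_intervals - 1
    vals[, f] <- codes
  }
  out <- table
  out$values <- vals
  out$discretized <- n_intervals
  out
}

#' Zero-inflation profile and suggested leaf nodes
#'
#' Counts exact zeros per feature. Heavily zero-inflated features (e.g.
#' CD4 T cells and Neutrophils in the breast-cancer cohort, with 350 and
#' 439 zero samples of 582) carry little rank information in their non-zero
#' tail, and arcs out of them are liable to be spurious; such features are
#' suggested as leaf nodes. The suggestion threshold is inclusive:
#' a zero fraction exactly equal to `zero_leaf_fraction` suggests a leaf.
#' Suggestions are advisory; roles remain user-confirmed.
#'
#' @param table a [feature_table()].
#' @param zero_leaf_fraction threshold in (0, 1], default 0.5.
#' @return data.frame with columns `feature`, `n_zero`, `zero_fraction`,
#'   `suggest_leaf`.
#' @export
zero_profile <- function(table, zero_leaf_fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (zero_leaf_fraction <= 0 || zero_leaf_fraction > 1)
    stop("zero_leaf_fraction must be in (0, 1]")
  cont <- table$feature_names[table$column_kind == "continuous"]
  n <- nrow(table$values)
  nz <- vapply(cont, function(f) sum(table$values[, f] == 0), numeric(1))
  data.frame(feature = cont, n_zero = as.integer(nz),
             zero_fraction = nz / n,
             suggest_leaf = (nz / n) >= zero_leaf_fraction,
             row.names = NULL)
}
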