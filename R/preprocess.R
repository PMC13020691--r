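# Preprocessing: mean imputation, correlation-based feature pruning and
# z-score normalization, with fit-on-train / apply-on-test semantics so the
# exact same transformation is reused across bootstraps and CV folds.

#' Fit the preprocessing model
#'
#' Computes per-column imputation means (ignoring missing entries), imputes,
#' drops zero-variance columns, prunes highly correlated features (for each
#' pair with `|r| > corr_threshold` the later column in the original order
#' is dropped), and records mean/SD scale parameters for the surviving
#' columns.
#'
#' @param features Numeric matrix or data frame (observations x features).
#' @param corr_threshold Absolute Pearson correlation above which the later
#'   column of a pair is dropped. Default 0.95.
#' @return An object of class `preprocess_model`.
#' @export
fit_preprocess <- function(features, corr_threshold = 0.95) {
  x <- stop_if_not_matrix(features, "features")
  if (nrow(x) < 2L) stop("need at least 2 observations")
  if (ncol(x) < 1L) stop("need at least 1 feature")
  stopifnot(corr_threshold > 0, corr_threshold <= 1)
  cn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  all_missing <- which(colSums(!is.na(x)) == 0L)
  if (length(all_missing))
    stop(sprintf("column '%s' is entirely missing", cn[all_missing[1L]]))
  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- col_means[j]

  sds <- apply(x, 2L, stats::sd)
  candidate <- unname(which(sds > 1e-12))
  kept <- integer(0)
  if (length(candidate)) {
    cmat <- abs(stats::cor(x[, candidate, drop = FALSE]))
    dropped <- rep(FALSE, length(candidate))
    for (j in seq_along(candidate)) {
      if (dropped[j]) next
      kept <- c(kept, candidate[j])
      if (j < length(candidate)) {
        later <- (j + 1L):length(candidate)
        dropped[later] <- dropped[later] | cmat[j, later] > corr_threshold
      }
    }
  }
  if (!length(kept)) stop("no columns survive preprocessing")
  structure(list(
    column_means = col_means,
    kept_columns = kept,
    scale_center = colMeans(x[, kept, drop = FALSE]),
    scale_sd = apply(x[, kept, drop = FALSE], 2L, stats::sd),
    corr_threshold = corr_threshold,
    input_width = ncol(x),
    input_names = cn
  ), class = "preprocess_model")
}

#' Apply a fitted preprocessing model
#'
#' Imputes missing entries with the stored training means, subsets to the
#' kept columns and z-scores with the stored training scale parameters.
#' Applying the model to its own training data yields columns with mean 0
#' and SD 1.
#'
#' @param model A `preprocess_model`.
#' @param features Matrix with the same width as the training data.
#' @return Numeric matrix with `length(model$kept_columns)` columns.
#' @export
apply_preprocess <- function(model, features) {
  stopifnot(inherits(model, "preprocess_model"))
  x <- stop_if_not_matrix(features, "features")
  if (ncol(x) != model$input_width)
    stop(sprintf("feature width %d does not match fitted width %d",
                 ncol(x), model$input_width))
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- model$column_means[j]
  x <- x[, model$kept_columns, drop = FALSE]
  x <- sweep(sweep(x, 2L, model$scale_center, "-"), 2L, model$scale_sd, "/")
  colnames(x) <- model$input_names[model$kept_columns]
  x
}

#' @export
print.preprocess_model <- function(x, ...) {
  cat(sprintf("preprocess_model: %d of %d columns kept (|r| threshold %.2f)\n",
              length(x$kept_columns), x$input_width, x$corr_threshold))
  invisible(x)
}

#' Serialize / restore a preprocessing model as JSON
#'
#' @param model A `preprocess_model`.
#' @param path File path.
#' @return `preprocess_to_json` returns `path` invisibly;
#'   `preprocess_from_json` returns the restored `preprocess_model`.
#' @export
preprocess_to_json <- function(model, path) {
  stopifnot(inherits(model, "preprocess_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname preprocess_to_json
#' @export
preprocess_from_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$kept_columns <- as.integer(m$kept_columns)
  m$input_width <- as.integer(m$input_width)
  class(m) <- "preprocess_model"
  m
}
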