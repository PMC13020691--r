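# Evaluation statistics: adjusted Rand index, Davies-Bouldin index,
# Cramer's V, decision-tree interpretability accuracy, and
# logistic-regression AUROC outcome association.

#' Adjusted Rand index between two partitions
#'
#' Permutation-model chance-corrected Rand index computed from the
#' contingency table of the two label vectors. Equals 1 for partitions
#' identical up to relabeling and 0 in expectation for independent
#' partitions; comparing any partition with the single-cluster partition
#' yields 0 (the index equals its expectation). Positions missing in either
#' vector are dropped pairwise.
#'
#' @param labels_a,labels_b Label vectors of equal length.
#' @return A number in [-1, 1], or `NA` if fewer than 2 complete pairs.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  n <- length(a)
  if (n < 2L) return(NA_real_)
  tab <- table(a, b)
  sum_comb <- sum(choose(tab, 2))
  comb_a <- sum(choose(rowSums(tab), 2))
  comb_b <- sum(choose(colSums(tab), 2))
  expected <- comb_a * comb_b / choose(n, 2)
  max_index <- (comb_a + comb_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index))
    return(as.numeric(abs(sum_comb - max_index) <
                        .Machine$double.eps * max(1, max_index)))
  (sum_comb - expected) / (max_index - expected)
}

#' Davies-Bouldin index
#'
#' Mean over clusters i of `max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the
#' mean Euclidean distance of cluster-i points to their centroid (the
#' arithmetic mean) and `M_ij` the distance between centroids. Lower is
#' better; 0 for singleton clusters at distinct points.
#'
#' @param points Numeric matrix of coordinates.
#' @param labels Cluster label per row; `NA` rows are dropped.
#' @return Nonnegative number, or `NA` if fewer than 2 nonempty clusters or
#'   centroids coincide (flagged via `attr(, "flag")`).
#' @export
davies_bouldin <- function(points, labels) {
  x <- stop_if_not_matrix(points, "points")
  if (length(labels) != nrow(x)) stop("labels length must match rows")
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (!all(is.finite(x))) stop("coordinates must be finite")
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2L) return(structure(NA_real_, flag = "fewer than 2 clusters"))
  centroids <- rowsum(x, labels) / as.vector(table(labels))
  S <- vapply(seq_len(k), function(i) {
    xi <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2L, centroids[i, ], "-")^2)))
  }, numeric(1))
  M <- sqrt(cross_dist2(centroids, centroids))
  if (any(M[upper.tri(M)] < .Machine$double.eps))
    return(structure(NA_real_, flag = "coincident centroids"))
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Cramer's V between two categorical vectors
#'
#' `V = sqrt((chi^2 / n) / min(r - 1, c - 1))` from the contingency table,
#' without bias correction; invariant to relabeling either side, so it
#' compares clusterings without requiring matching labels or cluster
#' counts. If either side is constant, returns 0 with a `"constant"` flag
#' attribute.
#'
#' @param labels_a,labels_b Label vectors of equal length; `NA` positions
#'   dropped pairwise.
#' @return A number in [0, 1].
#' @export
cramers_v <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  keep <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[keep]; b <- labels_b[keep]
  n <- length(a)
  if (n < 1L) return(NA_real_)
  tab <- table(a, b)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(structure(0, flag = "constant"))
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  sqrt((chi2 / n) / min(nrow(tab) - 1L, ncol(tab) - 1L))
}

#' Cross-validated decision-tree interpretability accuracy
#'
#' Overall 10-fold cross-validated accuracy (%) of an impurity-based
#' classification tree ([rpart::rpart()]) predicting cluster membership
#' from the (preprocessed) features — the likelihood that a feature profile
#' can be constructed to represent the clusters.
#'
#' @param features Numeric feature matrix.
#' @param labels Cluster labels; `NA` rows are dropped.
#' @param cfg Optional list: `n_folds` (10), `seed` (1), `cp` (0.01),
#'   `maxdepth` (30), `minsplit` (20).
#' @return Accuracy percentage in [0, 100], or `NA` for a single cluster.
#' @export
interpretability_accuracy <- function(features, labels, cfg = list()) {
  x <- stop_if_not_matrix(features, "features")
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  if (length(unique(labels)) < 2L) return(NA_real_)
  n_folds <- cfg$n_folds %||% 10L
  seed <- cfg$seed %||% 1L
  df <- data.frame(.cluster = factor(labels), x, check.names = TRUE)
  fold_of <- withr::with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = nrow(df))))
  pred <- rep(NA_character_, nrow(df))
  ctrl <- rpart::rpart.control(cp = cfg$cp %||% 0.01,
                               maxdepth = cfg$maxdepth %||% 30L,
                               minsplit = cfg$minsplit %||% 20L)
  for (f in seq_len(n_folds)) {
    test <- fold_of == f
    if (!any(test) || length(unique(df$.cluster[!test])) < 2L) next
    tree <- rpart::rpart(.cluster ~ ., data = df[!test, , drop = FALSE],
                         method = "class", control = ctrl)
    pred[test] <- as.character(stats::predict(tree, df[test, , drop = FALSE],
                                              type = "class"))
  }
  100 * mean(pred == as.character(df$.cluster), na.rm = TRUE)
}

#' Outcome association of cluster membership (logistic AUROC)
#'
#' Fits a logistic regression of a binary outcome on cluster membership as
#' a categorical predictor and returns the AUROC of the fitted
#' probabilities (their rank-based concordance with the outcome).
#'
#' @param labels Cluster labels; `NA` dropped pairwise with the outcome.
#' @param outcome_binary Binary outcome (0/1, logical, or 2-level factor).
#' @return AUROC in [0, 1], or `NA` for a constant outcome or single
#'   cluster.
#' @export
outcome_association <- function(labels, outcome_binary) {
  if (length(labels) != length(outcome_binary))
    stop("labels and outcome differ in length")
  y <- outcome_binary
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.numeric(y)
  keep <- !is.na(labels) & !is.na(y)
  labels <- labels[keep]; y <- y[keep]
  if (length(unique(y)) < 2L) return(NA_real_)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(labels)) < 2L) return(NA_real_)
  fit <- stats::glm(y ~ factor(labels), family = stats::binomial())
  p <- stats::fitted(fit)
  as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Pairwise Cramer's V concordance matrix across pipelines
#'
#' @param assignments Named list of cluster-label vectors (or
#'   `cluster_assignment` objects) over the same observations.
#' @return Symmetric matrix of pairwise Cramer's V with unit diagonal;
#'   rows/columns of pipelines whose labels are entirely `NA` are `NA`.
#' @export
concordance_matrix <- function(assignments) {
  labels <- lapply(assignments, function(a) {
    if (inherits(a, "cluster_assignment")) a$labels else a
  })
  n <- unique(vapply(labels, length, integer(1)))
  if (length(n) != 1L) stop("assignments cover different observation sets")
  m <- length(labels)
  ids <- names(labels) %||% paste0("P", seq_len(m))
  out <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  ok <- vapply(labels, function(l) any(!is.na(l)), logical(1))
  for (i in seq_len(m)) {
    if (ok[i]) out[i, i] <- 1
    if (i < m) for (j in (i + 1L):m) {
      if (ok[i] && ok[j]) {
        v <- as.numeric(cramers_v(labels[[i]], labels[[j]]))
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}
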