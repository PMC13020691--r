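# Effect-size-controlled Gaussian-mixture benchmark simulator.
#
# Benchmark datasets are mixtures of K = 3 multivariate normals whose
# parameters are derived from a labeled reference table (by default the
# classic three-species, four-feature Iris measurements shipped with R).
# Component means are pulled toward or pushed away from the grand mean so
# that the average relative between-class mean separation hits a target
# level (~10 / 20 / 50 %), and independent standard-normal noise covariates
# are appended to control dimensionality.

EFFECT_TARGETS <- c(small = 0.10, medium = 0.20, large = 0.50)

#' Reference data for mixture-parameter derivation
#'
#' Returns the built-in three-class, four-feature reference table (Fisher's
#' Iris measurements from the \pkg{datasets} package): 150 observations,
#' 50 per class, no missing values.
#'
#' @return A list with `features` (150 x 4 numeric matrix, columns
#'   `f1..f4`) and `class_labels` (integer vector in 1..3).
#' @export
iris_reference <- function() {
  x <- as.matrix(datasets::iris[, 1:4])
  colnames(x) <- paste0("f", 1:4)
  ref <- list(features = x, class_labels = as.integer(datasets::iris$Species))
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  x <- stop_if_not_matrix(ref$features, "features")
  lab <- ref$class_labels
  if (anyNA(x)) stop("reference features contain missing values")
  if (length(lab) != nrow(x)) stop("class_labels length must match rows")
  tab <- table(lab)
  if (length(tab) != 3L) stop("reference must have exactly 3 classes")
  invisible(ref)
}

#' Mean relative between-class separation of a set of component means
#'
#' Average over all class pairs and all features of
#' `|mu_jf - mu_kf| / |mubar_f|`, where `mubar` is the grand mean of the
#' class means. This is the quantity the effect levels (~0.10/0.20/0.50)
#' are calibrated against.
#'
#' @param means K x p matrix of component means.
#' @param grand_mean Optional length-p grand mean; defaults to the column
#'   mean of `means`.
#' @return A single nonnegative number.
#' @export
mean_separation <- function(means, grand_mean = colMeans(means)) {
  K <- nrow(means)
  pairs <- utils::combn(K, 2L)
  diffs <- apply(pairs, 2L, function(jk) {
    abs(means[jk[1L], ] - means[jk[2L], ]) / abs(grand_mean)
  })
  mean(diffs)
}

#' Derive mixture parameters at a target effect level
#'
#' Computes per-class sample means and covariances from the reference, then
#' rescales the class means about the grand mean,
#' `mu_k(s) = mubar + s (mu_k - mubar)`, choosing the scale `s` so that the
#' mean relative separation (see [mean_separation()]) equals the target for
#' the requested effect level: small ~0.10, medium ~0.20, large ~0.50.
#' Covariances are the per-class sample covariances, unscaled; mixing
#' proportions are equal.
#'
#' @param ref Reference list as returned by [iris_reference()].
#' @param effect_level One of `"small"`, `"medium"`, `"large"`.
#' @param target Optional numeric target separation overriding the level.
#' @return An object of class `mixture_params`: component means (K x p),
#'   covariances (list of p x p), mixing proportions, the applied scale
#'   `effect_scale`, and the achieved separation.
#' @export
derive_mixture_params <- function(ref, effect_level = c("small", "medium", "large"),
                                  target = NULL) {
  validate_reference(ref)
  effect_level <- match.arg(effect_level)
  if (is.null(target)) target <- EFFECT_TARGETS[[effect_level]]
  x <- ref$features
  lab <- ref$class_labels
  classes <- sort(unique(lab))
  K <- length(classes)
  means <- t(vapply(classes, function(k) colMeans(x[lab == k, , drop = FALSE]),
                    numeric(ncol(x))))
  covs <- lapply(classes, function(k) {
    xs <- x[lab == k, , drop = FALSE]
    if (nrow(xs) < 2L) stop(sprintf("class %s has fewer than 2 observations", k))
    stats::cov(xs)
  })
  grand <- colMeans(means)
  base_sep <- mean_separation(means, grand)
  if (!is.finite(base_sep) || base_sep <= 0)
    stop("reference classes have zero baseline mean separation; target unreachable")
  s <- target / base_sep
  scaled <- sweep(sweep(means, 2L, grand, "-") * s, 2L, grand, "+")
  out <- list(
    component_means = scaled,
    component_covariances = covs,
    mixing_proportions = rep(1 / K, K),
    effect_scale = s,
    effect_level = effect_level,
    target_separation = target,
    achieved_separation = mean_separation(scaled, grand),
    feature_names = colnames(x)
  )
  class(out) <- "mixture_params"
  out
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("mixture_params: %d components, %d features\n",
              nrow(x$component_means), ncol(x$component_means)))
  cat(sprintf("  effect level %s, scale s = %.4f, achieved separation %.4f\n",
              x$effect_level, x$effect_scale, x$achieved_separation))
  invisible(x)
}

#' Simulation configuration
#'
#' @param effect_level One of `"small"`, `"medium"`, `"large"`.
#' @param n_obs Number of observations (default 1000).
#' @param n_noise Number of appended standard-normal noise covariates.
#' @param seed Integer seed controlling the draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(effect_level = "large", n_obs = 1000L, n_noise = 0L,
                       seed = 1L) {
  stopifnot(n_obs >= 3L, n_noise >= 0L)
  structure(list(effect_level = effect_level, n_obs = as.integer(n_obs),
                 n_noise = as.integer(n_noise), seed = as.integer(seed)),
            class = "sim_config")
}

check_psd <- function(sigma, k) {
  if (!isSymmetric(unname(sigma), tol = 1e-8))
    stop(sprintf("covariance of component %d is not symmetric", k))
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop(sprintf("covariance of component %d is not positive semi-definite", k))
}

#' Simulate a benchmark dataset from mixture parameters
#'
#' Each observation's component is drawn from the mixing proportions; its
#' informative features from that component's multivariate normal; noise
#' covariates are i.i.d. N(0, 1), independent of the component. The draw is
#' deterministic given `config$seed`.
#'
#' @param params A `mixture_params` object.
#' @param config A `sim_config` object.
#' @return An object of class `sim_dataset`: `features`
#'   (n_obs x (p + n_noise) matrix, columns `f1..fp`, `noise1..noiseN`),
#'   `ground_truth` (integer component labels), `config`, `params`.
#' @export
simulate_dataset <- function(params, config) {
  stopifnot(inherits(params, "mixture_params"), inherits(config, "sim_config"))
  K <- nrow(params$component_means)
  p <- ncol(params$component_means)
  for (k in seq_len(K)) check_psd(params$component_covariances[[k]], k)
  n <- config$n_obs
  feats <- matrix(NA_real_, n, p)
  withr::with_seed(config$seed, {
    comp <- sample.int(K, n, replace = TRUE, prob = params$mixing_proportions)
    for (k in seq_len(K)) {
      idx <- which(comp == k)
      if (length(idx))
        feats[idx, ] <- MASS::mvrnorm(length(idx), params$component_means[k, ],
                                      params$component_covariances[[k]])
    }
    noise <- if (config$n_noise > 0L)
      matrix(stats::rnorm(n * config$n_noise), n) else NULL
  })
  colnames(feats) <- params$feature_names %||% paste0("f", seq_len(p))
  if (!is.null(noise)) {
    colnames(noise) <- paste0("noise", seq_len(config$n_noise))
    feats <- cbind(feats, noise)
  }
  structure(list(features = feats, ground_truth = comp, config = config,
                 params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d obs x %d features (%s effect, %d noise covariates)\n",
              nrow(x$features), ncol(x$features), x$config$effect_level,
              x$config$n_noise))
  invisible(x)
}

#' Write / read a simulated dataset as delimited text
#'
#' The dataset is written as a comma-separated table with header
#' `obs_id, <features...>, ground_truth`, plus a JSON sidecar
#' (`<path>.json`) carrying the mixture parameters and simulation
#' configuration for provenance. `read_dataset` checks for a well-formed
#' header and rectangular rows and reports the first offending line.
#'
#' @param ds A `sim_dataset`.
#' @param path Output CSV path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   a `sim_dataset` (with `config`/`params` restored from the sidecar when
#'   present).
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "sim_dataset"))
  df <- data.frame(obs_id = seq_len(nrow(ds$features)), ds$features,
                   ground_truth = ds$ground_truth, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(config = unclass(ds$config),
               params = serialize_params(ds$params))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

serialize_params <- function(p) {
  if (is.null(p)) return(NULL)
  list(component_means = p$component_means,
       component_covariances = p$component_covariances,
       mixing_proportions = p$mixing_proportions,
       effect_scale = p$effect_scale,
       effect_level = p$effect_level,
       target_separation = p$target_separation,
       achieved_separation = p$achieved_separation,
       feature_names = p$feature_names)
}

deserialize_params <- function(lst) {
  if (is.null(lst)) return(NULL)
  lst$component_means <- as.matrix(lst$component_means)
  lst$component_covariances <- lapply(lst$component_covariances, as.matrix)
  lst$mixing_proportions <- as.numeric(lst$mixing_proportions)
  class(lst) <- "mixture_params"
  lst
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop(sprintf("%s: empty or header-only file", path))
  nf <- utils::count.fields(path, sep = ",", quote = "")
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "obs_id" || !("ground_truth" %in% header))
    stop(sprintf("%s: header must contain obs_id first and a ground_truth column",
                 path))
  df <- utils::read.csv(path, check.names = FALSE)
  feat_cols <- setdiff(names(df), c("obs_id", "ground_truth"))
  feats <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!is.numeric(feats)) stop(sprintf("%s: non-numeric feature values", path))
  side_path <- paste0(path, ".json")
  config <- NULL; params <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    config <- structure(as.list(side$config), class = "sim_config")
    params <- deserialize_params(side$params)
  }
  structure(list(features = feats, ground_truth = as.integer(df$ground_truth),
                 config = config, params = params),
            class = "sim_dataset")
}
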