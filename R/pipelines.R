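# The ten dimensionality-reduction -> clustering chains and a uniform
# out-of-sample cluster-assignment path. K-means pipelines assign new data
# to the nearest centroid; spectral pipelines use a k-nearest-neighbour
# surrogate in the final reduced space (spectral clustering retains no
# out-of-sample map); t-SNE pipelines re-embed training and new points
# jointly, which is deliberately faithful to t-SNE's lack of a stored
# transformation and is expected to be unstable.

PIPELINE_STAGES <- list(
  M1  = "kmeans",
  M2  = c("kernel_pca", "kmeans"),
  M3  = c("nmf", "kernel_pca", "kmeans"),
  M4  = c("nmf", "kmeans"),
  M5  = "spectral",
  M6  = c("kernel_pca", "spectral"),
  M7  = c("nmf", "kernel_pca", "spectral"),
  M8  = c("nmf", "spectral"),
  M9  = c("kernel_pca", "tsne", "kmeans"),
  M10 = c("tsne", "kmeans")
)

#' Pipeline identifiers
#'
#' @return Character vector `M1..M10`.
#' @export
pipeline_ids <- function() names(PIPELINE_STAGES)

default_stage_hyperparams <- function(kind) {
  switch(kind,
    kernel_pca = list(kernel = "linear", n_components = 2L),
    nmf = list(n_components = 5L),
    tsne = list(perplexity = 30),
    kmeans = list(n_clusters = 3L),
    spectral = list(n_clusters = 3L)
  )
}

#' Construct a pipeline specification
#'
#' Builds the ordered stage chain for one of the ten predefined pipelines:
#' M1 K-means; M2 PCA->K-means; M3 NMF->PCA->K-means; M4 NMF->K-means;
#' M5 Spectral; M6 PCA->Spectral; M7 NMF->PCA->Spectral; M8 NMF->Spectral;
#' M9 PCA->t-SNE->K-means; M10 t-SNE->K-means. "PCA" is kernel PCA whose
#' kernel (linear by default) is itself searchable.
#'
#' @param pipeline_id One of `pipeline_ids()`.
#' @param hyperparams Named list of hyperparameter values, names of the form
#'   `<stage_kind>.<param>` (e.g. `kmeans.n_clusters`, `nmf.n_components`,
#'   `kernel_pca.kernel`, `kernel_pca.n_components`, `tsne.perplexity`,
#'   `spectral.n_clusters`). Unset values take stage defaults.
#' @return An object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(pipeline_id, hyperparams = list()) {
  pipeline_id <- match.arg(pipeline_id, pipeline_ids())
  kinds <- PIPELINE_STAGES[[pipeline_id]]
  stages <- lapply(kinds, function(kind) {
    hp <- default_stage_hyperparams(kind)
    prefix <- paste0(kind, ".")
    for (nm in names(hyperparams)) {
      if (startsWith(nm, prefix)) {
        par <- substring(nm, nchar(prefix) + 1L)
        if (!par %in% stage_hyperparam_names[[kind]])
          stop(sprintf("'%s' is not a hyperparameter of stage '%s'", par, kind))
        hp[[par]] <- hyperparams[[nm]]
      }
    }
    list(kind = kind, hyperparams = hp)
  })
  bad <- vapply(names(hyperparams), function(nm) {
    !any(vapply(kinds, function(k) startsWith(nm, paste0(k, ".")), logical(1)))
  }, logical(1))
  if (any(bad))
    stop(sprintf("hyperparameter '%s' matches no stage of %s",
                 names(hyperparams)[bad][1L], pipeline_id))
  structure(list(pipeline_id = pipeline_id, stages = stages),
            class = "pipeline_spec")
}

#' @export
print.pipeline_spec <- function(x, ...) {
  chain <- vapply(x$stages, function(s) {
    hp <- paste(names(s$hyperparams),
                vapply(s$hyperparams, function(v) paste(format(v), collapse = ","),
                       character(1)),
                sep = "=", collapse = ", ")
    sprintf("%s(%s)", s$kind, hp)
  }, character(1))
  cat(sprintf("%s: %s\n", x$pipeline_id, paste(chain, collapse = " -> ")))
  invisible(x)
}

#' Control options shared by pipeline fitting
#'
#' @param knn_k Neighbours for the spectral out-of-sample surrogate.
#' @param kmeans_nstart Random restarts for K-means.
#' @param tsne_max_iter Gradient-descent iterations for t-SNE.
#' @param spectral_sigma RBF affinity bandwidth for spectral clustering;
#'   `NULL` (default) uses the median pairwise distance of the input.
#' @param nmf_maxiter,nmf_tol NMF multiplicative-update budget and relative
#'   convergence tolerance.
#' @return A list of class `pipeline_control`.
#' @export
pipeline_control <- function(knn_k = 5L, kmeans_nstart = 10L,
                             tsne_max_iter = 500L, spectral_sigma = NULL,
                             nmf_maxiter = 200L, nmf_tol = 1e-4) {
  structure(list(knn_k = as.integer(knn_k),
                 kmeans_nstart = as.integer(kmeans_nstart),
                 tsne_max_iter = as.integer(tsne_max_iter),
                 spectral_sigma = spectral_sigma,
                 nmf_maxiter = as.integer(nmf_maxiter), nmf_tol = nmf_tol),
            class = "pipeline_control")
}

#' Fit a pipeline on a training matrix
#'
#' Fits the dimensionality-reduction stages sequentially (each consuming
#' the previous stage's output; NMF stages min-max rescale their input to
#' `[0, 1]` first) and the terminal clustering stage on the final reduced
#' representation. Deterministic given `seed`.
#'
#' @param spec A `pipeline_spec`.
#' @param train_matrix Preprocessed numeric matrix (no missing values).
#' @param seed Integer seed for the stochastic stages.
#' @param control A [pipeline_control()] list.
#' @return An object of class `fitted_pipeline` with the fitted stages,
#'   `train_labels`, `reduced_train` (training data in the final reduced
#'   space) and convergence flags.
#' @export
fit_pipeline <- function(spec, train_matrix, seed = 1L,
                         control = pipeline_control()) {
  stopifnot(inherits(spec, "pipeline_spec"))
  x <- stop_if_not_matrix(train_matrix, "train_matrix")
  if (anyNA(x) || !all(is.finite(x))) stop("train_matrix must be finite")
  cur <- unname(x)
  fitted <- vector("list", length(spec$stages))
  flags <- character(0)
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    stage_seed <- derive_seed(seed, "stage", i, st$kind)
    fitted[[i]] <- fit_stage(st$kind, cur, st$hyperparams, stage_seed, control)
    if (isFALSE(fitted[[i]]$converged))
      flags <- c(flags, sprintf("%s stage did not converge", st$kind))
    if (!st$kind %in% CLUSTER_KINDS) {
      # training representation comes from the fit itself where one exists
      cur <- switch(st$kind,
                    tsne = fitted[[i]]$train_embedding,
                    nmf = fitted[[i]]$fit$W,
                    transform_stage(fitted[[i]], cur))
    }
  }
  terminal <- fitted[[length(fitted)]]
  structure(list(
    spec = spec, stages = fitted, train_labels = terminal$labels,
    reduced_train = cur, train_width = ncol(x), control = control,
    seed = seed, flags = flags
  ), class = "fitted_pipeline")
}

#' @export
print.fitted_pipeline <- function(x, ...) {
  cat(sprintf("fitted %s: %d training observations, %d clusters%s\n",
              x$spec$pipeline_id, length(x$train_labels),
              length(unique(x$train_labels)),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}

has_tsne <- function(fp) any(vapply(fp$stages, function(s) s$kind == "tsne",
                                    logical(1)))

# Apply the stored DR stages to new data; for t-SNE pipelines the t-SNE
# stage is refitted jointly on train + new and both coordinate sets are
# returned so assignment and geometry share one embedding.
push_through_dr <- function(fp, newx) {
  cur <- unname(newx)
  train_coords <- NULL
  for (st in fp$stages) {
    if (st$kind %in% CLUSTER_KINDS) break
    if (st$kind == "tsne") {
      joint <- tsne_joint_embed(st, cur)
      cur <- joint$new
      train_coords <- joint$train
    } else {
      cur <- transform_stage(st, cur)
    }
  }
  if (is.null(train_coords)) train_coords <- fp$reduced_train
  list(new = cur, train = train_coords)
}

assign_with_reduced <- function(fp, newx) {
  terminal <- fp$stages[[length(fp$stages)]]
  pushed <- push_through_dr(fp, newx)
  labels <- if (terminal$kind == "kmeans") {
    if (has_tsne(fp)) {
      # centroids recomputed from the training labels in the joint embedding
      labs <- sort(unique(fp$train_labels))
      centers <- rowsum(pushed$train, fp$train_labels) /
        as.vector(table(fp$train_labels))
      labs[nearest_centroid(centers, pushed$new)]
    } else {
      nearest_centroid(terminal$centers, pushed$new)
    }
  } else {
    knn_majority(pushed$train, fp$train_labels, pushed$new,
                 k = fp$control$knn_k)
  }
  list(labels = as.integer(labels), reduced = pushed$new)
}

#' Assign cluster labels to new observations
#'
#' Pushes new data through the stored dimensionality-reduction stages and
#' assigns clusters: K-means pipelines by nearest centroid (ties to the
#' smallest label), spectral pipelines by majority vote among the `knn_k`
#' nearest training points in the final reduced space (ties to the smallest
#' label), and t-SNE pipelines by re-embedding training and new points
#' jointly before assignment.
#'
#' @param fp A `fitted_pipeline`.
#' @param new_matrix Matrix with the training width; may have zero rows.
#' @return Integer vector of cluster labels drawn from the fitted label set.
#' @export
assign_out_of_sample <- function(fp, new_matrix) {
  stopifnot(inherits(fp, "fitted_pipeline"))
  x <- stop_if_not_matrix(new_matrix, "new_matrix")
  if (nrow(x) == 0L) return(integer(0))
  if (ncol(x) != fp$train_width)
    stop(sprintf("width %d does not match training width %d",
                 ncol(x), fp$train_width))
  assign_with_reduced(fp, x)$labels
}

#' Reduced representation of data under a fitted pipeline
#'
#' Applies the stored dimensionality-reduction stages only (identity for
#' pipelines without DR stages). For t-SNE pipelines the embedding is
#' refitted jointly with the stored training points.
#'
#' @param fp A `fitted_pipeline`.
#' @param matrix_ Matrix with the training width.
#' @return Matrix in the final reduced space.
#' @export
reduced_representation <- function(fp, matrix_) {
  stopifnot(inherits(fp, "fitted_pipeline"))
  x <- stop_if_not_matrix(matrix_, "matrix_")
  if (ncol(x) != fp$train_width)
    stop(sprintf("width %d does not match training width %d",
                 ncol(x), fp$train_width))
  push_through_dr(fp, x)$new
}

#' Default hyperparameter grid for a pipeline
#'
#' Grid values per searchable hyperparameter: cluster count 2..6, component
#' counts {2, 5, 10, 20}, t-SNE perplexity {5, 15, 30, 50}, and the kernel
#' list for kernel PCA (linear only by default; pass
#' `kernels = c("linear", "rbf", ...)` to widen).
#'
#' @param pipeline_id One of `pipeline_ids()`.
#' @param n_clusters,n_components,perplexity,kernels Value vectors
#'   overriding the defaults.
#' @return Named list of value vectors keyed `<stage_kind>.<param>`.
#' @export
default_grid <- function(pipeline_id, n_clusters = 2:6,
                         n_components = c(2L, 5L, 10L, 20L),
                         perplexity = c(5, 15, 30, 50),
                         kernels = "linear") {
  pipeline_id <- match.arg(pipeline_id, pipeline_ids())
  grid <- list()
  for (kind in PIPELINE_STAGES[[pipeline_id]]) {
    grid <- c(grid, switch(kind,
      kernel_pca = stats::setNames(list(kernels, n_components),
                                   c("kernel_pca.kernel", "kernel_pca.n_components")),
      nmf = list(nmf.n_components = n_components),
      tsne = list(tsne.perplexity = perplexity),
      kmeans = list(kmeans.n_clusters = n_clusters),
      spectral = list(spectral.n_clusters = n_clusters)
    ))
  }
  grid
}
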