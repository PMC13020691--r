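# Stage-level fit/transform primitives behind the pipelines. Each stage is
# fitted on a training matrix and can transform new data with the stored
# state. Clustering stages (kmeans, spectral) are terminal and expose
# training labels plus the state needed for out-of-sample assignment.

STAGE_KINDS <- c("kernel_pca", "nmf", "tsne", "kmeans", "spectral")
CLUSTER_KINDS <- c("kmeans", "spectral")
KPCA_KERNELS <- c("sigmoid", "rbf", "linear", "cosine", "polynomial")

stage_hyperparam_names <- list(
  kernel_pca = c("kernel", "n_components"),
  nmf = "n_components",
  tsne = "perplexity",
  kmeans = "n_clusters",
  spectral = "n_clusters"
)

# cosine-similarity kernel for kernlab (zero vectors map to similarity 0)
cosine_kernel <- function() {
  k <- function(x, y) {
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) return(0)
    sum(x * y) / (nx * ny)
  }
  class(k) <- "kernel"
  k
}

make_kernel <- function(kernel, p) {
  switch(kernel,
    linear = kernlab::vanilladot(),
    rbf = kernlab::rbfdot(sigma = 1 / p),
    sigmoid = kernlab::tanhdot(scale = 1 / p, offset = 1),
    polynomial = kernlab::polydot(degree = 3, scale = 1 / p, offset = 1),
    cosine = cosine_kernel(),
    stop(sprintf("unknown kernel '%s'", kernel))
  )
}

fit_stage_kernel_pca <- function(x, hp, seed, control) {
  nc <- as.integer(hp$n_components %||% 2L)
  kernel <- hp$kernel %||% "linear"
  if (!kernel %in% KPCA_KERNELS) stop(sprintf("unknown kernel '%s'", kernel))
  if (nc > ncol(x) || nc >= nrow(x))
    stop(sprintf("n_components = %d exceeds available dimensions (%d x %d)",
                 nc, nrow(x), ncol(x)))
  if (kernel == "linear") {
    # linear-kernel PCA coincides with ordinary PCA on centered data
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nc)
    list(kind = "kernel_pca", kernel = kernel, n_components = nc, pr = pr)
  } else {
    kp <- kernlab::kpca(x, kernel = make_kernel(kernel, ncol(x)), features = nc)
    list(kind = "kernel_pca", kernel = kernel, n_components = nc, kp = kp)
  }
}

transform_stage_kernel_pca <- function(stage, x) {
  if (stage$kernel == "linear") {
    out <- stats::predict(stage$pr, x)[, seq_len(stage$n_components), drop = FALSE]
  } else {
    out <- kernlab::predict(stage$kp, x)[, seq_len(stage$n_components), drop = FALSE]
  }
  unname(as.matrix(out))
}

fit_stage_nmf <- function(x, hp, seed, control) {
  nc <- as.integer(hp$n_components %||% 5L)
  if (nc > ncol(x))
    stop(sprintf("n_components = %d exceeds input width %d", nc, ncol(x)))
  mm <- minmax_fit(x)          # NMF needs nonnegative input; z-scores are not
  fit <- nmf_fit(minmax_apply(mm, x), rank = nc,
                 maxiter = control$nmf_maxiter, tol = control$nmf_tol)
  list(kind = "nmf", n_components = nc, mm = mm, fit = fit,
       converged = fit$converged)
}

transform_stage_nmf <- function(stage, x) {
  unname(nmf_transform(stage$fit, minmax_apply(stage$mm, x)))
}

fit_stage_tsne <- function(x, hp, seed, control) {
  perplexity <- as.numeric(hp$perplexity %||% 30)
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  emb <- withr::with_seed(seed, Rtsne::Rtsne(
    x, dims = 2L, perplexity = perplexity, check_duplicates = FALSE,
    pca = FALSE, max_iter = control$tsne_max_iter, verbose = FALSE))$Y
  list(kind = "tsne", perplexity = perplexity, train_input = x,
       train_embedding = emb, seed = seed, max_iter = control$tsne_max_iter)
}

# t-SNE retains no out-of-sample map: new points are embedded by refitting
# jointly with the stored training input. Returns coordinates for both the
# training points and the new points in the shared refitted embedding.
tsne_joint_embed <- function(stage, newx) {
  n_train <- nrow(stage$train_input)
  joint <- rbind(stage$train_input, newx)
  perplexity <- min(stage$perplexity, floor((nrow(joint) - 1) / 3))
  emb <- withr::with_seed(stage$seed, Rtsne::Rtsne(
    joint, dims = 2L, perplexity = perplexity, check_duplicates = FALSE,
    pca = FALSE, max_iter = stage$max_iter, verbose = FALSE))$Y
  list(train = emb[seq_len(n_train), , drop = FALSE],
       new = emb[-seq_len(n_train), , drop = FALSE])
}

# Hartigan-Wong errors outright when random initial centers coincide
# (point-mass data, e.g. spectral embeddings of tight clusters); fall back
# to MacQueen, which tolerates such starts.
safe_kmeans <- function(x, k, nstart, seed) {
  withr::with_seed(seed,
    tryCatch(stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50L),
             error = function(e) suppressWarnings(
               stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50L,
                             algorithm = "MacQueen"))))
}

fit_stage_kmeans <- function(x, hp, seed, control) {
  k <- as.integer(hp$n_clusters %||% 3L)
  if (k < 2L || k > nrow(x)) stop(sprintf("invalid n_clusters = %d", k))
  km <- safe_kmeans(x, k, control$kmeans_nstart, seed)
  list(kind = "kmeans", n_clusters = k, centers = km$centers,
       labels = as.integer(km$cluster), objective = km$tot.withinss)
}

# Spectral clustering (normalized-cut embedding): RBF affinity with
# locally scaled bandwidths (sigma_i = distance to the 7th nearest
# neighbour, Zelnik-Manor & Perona) by default — a global bandwidth
# degenerates under distance concentration when the input is
# high-dimensional — then symmetric normalized Laplacian, top-k
# eigenvectors row-normalized, and K-means.
spectral_embed <- function(x, k, sigma = NULL, nn = 7L) {
  d2 <- cross_dist2(x, x)
  if (is.null(sigma)) {
    d <- sqrt(d2)
    nn <- min(nn, nrow(d) - 1L)
    # scale over positive distances only: bootstrap resamples duplicate
    # rows, and a zero bandwidth would disconnect the duplicated points
    sig <- apply(d, 1L, function(r) {
      rp <- r[r > 1e-12]
      if (!length(rp)) return(1)
      sort(rp)[min(nn, length(rp))]
    })
    sig <- pmax(sig, .Machine$double.eps)
    A <- exp(-d2 / outer(sig, sig))
  } else {
    A <- exp(-d2 / (2 * sigma^2))
  }
  diag(A) <- 0
  d <- rowSums(A)
  d[d <= 0] <- .Machine$double.eps
  dis <- 1 / sqrt(d)
  M <- A * tcrossprod(dis)
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U / rn
}

fit_stage_spectral <- function(x, hp, seed, control) {
  k <- as.integer(hp$n_clusters %||% 3L)
  if (k < 2L || k > nrow(x)) stop(sprintf("invalid n_clusters = %d", k))
  U <- spectral_embed(x, k, control$spectral_sigma)
  if (!all(is.finite(U))) stop("spectral embedding is not finite")
  km <- safe_kmeans(U, k, control$kmeans_nstart, seed)
  list(kind = "spectral", n_clusters = k, train_coords = x,
       labels = as.integer(km$cluster), knn_k = control$knn_k)
}

fit_stage <- function(kind, x, hp, seed, control) {
  switch(kind,
    kernel_pca = fit_stage_kernel_pca(x, hp, seed, control),
    nmf = fit_stage_nmf(x, hp, seed, control),
    tsne = fit_stage_tsne(x, hp, seed, control),
    kmeans = fit_stage_kmeans(x, hp, seed, control),
    spectral = fit_stage_spectral(x, hp, seed, control),
    stop(sprintf("unknown stage kind '%s'", kind))
  )
}

transform_stage <- function(stage, x) {
  switch(stage$kind,
    kernel_pca = transform_stage_kernel_pca(stage, x),
    nmf = transform_stage_nmf(stage, x),
    tsne = tsne_joint_embed(stage, x)$new,
    stop(sprintf("stage kind '%s' has no transform", stage$kind))
  )
}
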