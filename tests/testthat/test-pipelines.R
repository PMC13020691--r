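blobs <- make_blobs()
Xb <- scale(blobs$x)

test_that("pipeline specs follow the published chains and validate hyperparameters", {
  expect_equal(vapply(pipeline_spec("M3")$stages, `[[`, "", "kind"),
               c("nmf", "kernel_pca", "kmeans"))
  expect_equal(vapply(pipeline_spec("M9")$stages, `[[`, "", "kind"),
               c("kernel_pca", "tsne", "kmeans"))
  expect_equal(vapply(pipeline_spec("M5")$stages, `[[`, "", "kind"), "spectral")
  expect_error(pipeline_spec("M1", list(kmeans.bandwidth = 2)), "not a hyperparameter")
  expect_error(pipeline_spec("M1", list(nmf.n_components = 2)), "matches no stage")
})

test_that("all non-t-SNE pipelines recover two separable blobs exactly", {
  for (pid in c("M1", "M2", "M3", "M4", "M5", "M6", "M7", "M8")) {
    hp <- list()
    for (kind in stabpipe:::PIPELINE_STAGES[[pid]]) {
      hp[[paste0(kind, ".n_clusters")]] <- NULL
      if (kind %in% c("kmeans", "spectral")) hp[[paste0(kind, ".n_clusters")]] <- 2L
      if (kind == "nmf") hp[["nmf.n_components"]] <- 2L
      if (kind == "kernel_pca") hp[["kernel_pca.n_components"]] <- 2L
    }
    fp <- fit_pipeline(pipeline_spec(pid, hp), Xb, seed = 3)
    expect_equal(adjusted_rand_index(fp$train_labels, blobs$labels), 1,
                 info = pid)
    # out-of-sample assignment of the training data matches up to labels
    lab <- assign_out_of_sample(fp, Xb)
    expect_equal(adjusted_rand_index(lab, blobs$labels), 1, info = pid)
    expect_true(all(lab %in% fp$train_labels), info = pid)
  }
})

test_that("fits are deterministic under a fixed seed", {
  fp1 <- fit_pipeline(pipeline_spec("M4", list(nmf.n_components = 2L,
                                               kmeans.n_clusters = 2L)), Xb, seed = 11)
  fp2 <- fit_pipeline(pipeline_spec("M4", list(nmf.n_components = 2L,
                                               kmeans.n_clusters = 2L)), Xb, seed = 11)
  expect_identical(fp1$train_labels, fp2$train_labels)
  expect_identical(reduced_representation(fp1, Xb), reduced_representation(fp2, Xb))
})

test_that("K-means assignment equals training labels and breaks ties to the smaller label", {
  fp <- fit_pipeline(pipeline_spec("M1", list(kmeans.n_clusters = 2L)), Xb, seed = 5)
  expect_identical(assign_out_of_sample(fp, Xb), fp$train_labels)
  # synthetic fitted pipeline with two centroids equidistant from a probe
  mid <- matrix((fp$stages[[1]]$centers[1, ] + fp$stages[[1]]$centers[2, ]) / 2,
                nrow = 1)
  expect_identical(assign_out_of_sample(fp, mid), 1L)
  expect_identical(assign_out_of_sample(fp, Xb[0, , drop = FALSE]), integer(0))
})

test_that("spectral surrogate with k = 1 returns a training point's own label", {
  fp <- fit_pipeline(pipeline_spec("M5", list(spectral.n_clusters = 2L)), Xb,
                     seed = 7, control = pipeline_control(knn_k = 1L))
  i <- c(1L, 35L)
  expect_identical(assign_out_of_sample(fp, Xb[i, , drop = FALSE]),
                   fp$train_labels[i])
})

test_that("reduced representation honours the dimension contract", {
  fp1 <- fit_pipeline(pipeline_spec("M1", list(kmeans.n_clusters = 2L)), Xb, seed = 1)
  expect_equal(reduced_representation(fp1, Xb), unname(Xb), tolerance = 1e-12,
               ignore_attr = TRUE)
  fp2 <- fit_pipeline(pipeline_spec("M2", list(kernel_pca.n_components = 3L,
                                               kmeans.n_clusters = 2L)), Xb, seed = 1)
  expect_equal(ncol(reduced_representation(fp2, Xb)), 3L)
  expect_error(reduced_representation(fp2, Xb[, 1:2]), "width")
  expect_error(fit_pipeline(pipeline_spec("M2", list(kernel_pca.n_components = 10L,
                                                     kmeans.n_clusters = 2L)),
                            Xb, seed = 1), "n_components")
})

test_that("M1 and M2 with linear kernel at full rank share the K-means objective", {
  # Euclidean K-means is invariant to a full-rank orthogonal rotation
  fp1 <- fit_pipeline(pipeline_spec("M1", list(kmeans.n_clusters = 2L)), Xb, seed = 9)
  fp2 <- fit_pipeline(pipeline_spec("M2", list(kernel_pca.kernel = "linear",
                                               kernel_pca.n_components = ncol(Xb),
                                               kmeans.n_clusters = 2L)), Xb, seed = 9)
  o1 <- fp1$stages[[1]]$objective
  o2 <- fp2$stages[[2]]$objective
  expect_lt(abs(o1 - o2) / o1, 1e-6)
})

test_that("non-linear kernel PCA projections agree with kernlab on training data", {
  # two point masses leave most kernel eigenvalues near zero; kernlab
  # warns about that on both routes
  kp <- suppressWarnings(
    kernlab::kpca(Xb, kernel = kernlab::rbfdot(sigma = 1 / ncol(Xb)),
                  features = 2))
  fp <- suppressWarnings(
    fit_pipeline(pipeline_spec("M2", list(kernel_pca.kernel = "rbf",
                                          kernel_pca.n_components = 2L,
                                          kmeans.n_clusters = 2L)), Xb, seed = 1))
  ours <- reduced_representation(fp, Xb)
  ref <- kernlab::rotated(kp)[, 1:2]
  for (j in 1:2) # eigenvector sign is arbitrary
    expect_lt(min(max(abs(ours[, j] - ref[, j])), max(abs(ours[, j] + ref[, j]))),
              1e-6)
})

test_that("spectral clustering agrees with kernlab::specc on separable data", {
  sp <- withr::with_seed(1, kernlab::specc(Xb, centers = 2))
  fp <- fit_pipeline(pipeline_spec("M5", list(spectral.n_clusters = 2L)), Xb, seed = 1)
  expect_equal(adjusted_rand_index(fp$train_labels, sp@.Data), 1)
})

test_that("t-SNE pipelines produce labels from the fitted set on blob data", {
  fp <- fit_pipeline(pipeline_spec("M10", list(tsne.perplexity = 10,
                                               kmeans.n_clusters = 2L)), Xb, seed = 3)
  lab <- assign_out_of_sample(fp, Xb)
  expect_true(all(lab %in% sort(unique(fp$train_labels))))
  expect_equal(length(lab), nrow(Xb))
})
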