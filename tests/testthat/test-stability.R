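blobs <- make_blobs(n_per = 40L)
Xb <- scale(blobs$x)

test_that("bootstrap indices have the contracted shape and are seed-deterministic", {
  cfg <- search_config(n_bootstrap = 100L, seed = 4)
  idx <- bootstrap_indices(1000L, cfg)
  expect_length(idx, 100L)
  expect_true(all(vapply(idx, length, integer(1)) == 900L))
  expect_true(all(unlist(idx) >= 1L & unlist(idx) <= 1000L))
  expect_identical(idx, bootstrap_indices(1000L, cfg))
  # fraction 1 without replacement -> each vector a permutation of 1..n
  cfg2 <- search_config(n_bootstrap = 5L, bootstrap_fraction = 1,
                        sample_with_replacement = FALSE, seed = 4)
  for (v in bootstrap_indices(50L, cfg2)) expect_setequal(v, 1:50)
  expect_error(bootstrap_indices(1L, cfg), "n >= 2")
})

test_that("a trivially separable clustering is perfectly stable", {
  cfg <- search_config(n_bootstrap = 8L, seed = 21)
  rec <- score_combo(Xb, pipeline_spec("M1"), list(kmeans.n_clusters = 2L), cfg)
  expect_equal(rec$mean_ari, 1, tolerance = 1e-12)
  expect_equal(rec$n_valid_pairs, 7L)
  expect_identical(rec$failure_flag, "")
})

test_that("with two bootstraps the mean ARI equals the single pairwise ARI", {
  cfg <- search_config(n_bootstrap = 2L, seed = 3)
  idx <- bootstrap_indices(nrow(Xb), cfg)
  rec <- score_combo(Xb, pipeline_spec("M1"), list(kmeans.n_clusters = 2L), cfg)
  labs <- lapply(1:2, function(b) {
    fp <- fit_pipeline(pipeline_spec("M1", list(kmeans.n_clusters = 2L)),
                       Xb[idx[[b]], , drop = FALSE],
                       seed = derive_seed(cfg$seed, "boot", b))
    assign_out_of_sample(fp, Xb)
  })
  expect_equal(rec$mean_ari, adjusted_rand_index(labs[[1]], labs[[2]]),
               tolerance = 1e-12)
  expect_equal(rec$n_valid_pairs, 1L)
})

test_that("mean ARI is invariant to relabeling within bootstraps and near zero for random labels", {
  # permutation invariance via the ARI itself over many generated cases
  withr::with_seed(31, for (i in 1:25) {
    a <- sample(1:3, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    perm <- sample(1:3)
    expect_equal(adjusted_rand_index(perm[a], b), adjusted_rand_index(a, b),
                 tolerance = 1e-12)
  })
  # ARI between independent random partitions has mean 0
  withr::with_seed(32, {
    aris <- replicate(200, adjusted_rand_index(sample(1:3, 100, TRUE),
                                               sample(1:3, 100, TRUE)))
  })
  expect_lt(abs(mean(aris)), 3 * stats::sd(aris) / sqrt(length(aris)))
})

test_that("degenerate combos yield NA records with failure flags, not errors", {
  cfg <- search_config(n_bootstrap = 4L, seed = 5)
  # infeasible: more NMF components than columns
  rec <- score_combo(Xb, pipeline_spec("M4"),
                     list(nmf.n_components = 50L, kmeans.n_clusters = 2L), cfg)
  expect_true(is.na(rec$mean_ari))
  expect_match(rec$failure_flag, "n_components")
  # structurally invalid combos error before any fitting
  expect_error(score_combo(Xb, pipeline_spec("M4"),
                           list(kmeans.sigma = 1), cfg), "not a hyperparameter")
})

test_that("grid search enumerates the Cartesian product deterministically", {
  cfg <- search_config(n_bootstrap = 4L, seed = 6)
  grid <- list(nmf.n_components = c(2L, 3L, 50L), kmeans.n_clusters = c(2L, 3L))
  recs <- grid_search(Xb, pipeline_spec("M4"), grid, cfg)
  expect_length(recs, 6L)
  df <- as.data.frame(recs)
  # the infeasible component count is flagged; the rest are scored
  expect_equal(sum(is.na(df$mean_ari)), 2L)
  expect_true(all(grepl("n_components", df$failure_flag[is.na(df$mean_ari)])))
  recs2 <- grid_search(Xb, pipeline_spec("M4"), grid, cfg)
  expect_identical(as.data.frame(recs2), df)
  expect_error(grid_search(Xb, pipeline_spec("M4"), list(), cfg), "empty")
})

test_that("selection takes the lowest DBI inside the top-ARI short-list", {
  mk <- function(ari, dbi, i) {
    r <- stabpipe:::new_stability_record(list(k = i), ari, dbi,
                                         n_valid_pairs = 9L)
    r$combo_index <- i
    r
  }
  vals <- list(c(.9, 2.0), c(.88, 1.1), c(.87, 1.5), c(.86, 3.0), c(.85, 2.5),
               c(.5, 0.1))
  recs <- lapply(seq_along(vals), function(i) mk(vals[[i]][1], vals[[i]][2], i))
  cfg <- search_config(n_bootstrap = 4L, top_k_ari = 5L, seed = 1)
  sel <- select_combo(recs, cfg)
  # the DBI-0.1 record is outside the ARI top five and must not win
  expect_equal(sel$mean_ari, 0.88)
  expect_equal(sel$mean_dbi, 1.1)
  # invariant to record order permutations
  withr::with_seed(8, for (i in 1:10) {
    perm <- sample(seq_along(recs))
    expect_equal(select_combo(recs[perm], cfg)$mean_ari, 0.88)
  })
  # single valid record wins; all-NA errors
  expect_equal(select_combo(recs[2], cfg)$mean_ari, 0.88)
  na_rec <- stabpipe:::new_stability_record(list(), failure_flag = "x")
  expect_error(select_combo(list(na_rec), cfg), "no stable combination")
  # equal ARIs resolve by lowest DBI
  ties <- list(mk(.9, 2.0, 1), mk(.9, 0.5, 2), mk(.9, 1.0, 3))
  expect_equal(select_combo(ties, cfg)$mean_dbi, 0.5)
})

test_that("cross-validated membership recovers separable structure exactly", {
  cfg <- search_config(n_bootstrap = 4L, n_folds = 10L, seed = 13)
  cv <- cv_membership(Xb, pipeline_spec("M1"), list(kmeans.n_clusters = 2L), cfg)
  expect_equal(adjusted_rand_index(cv$labels, blobs$labels), 1)
  expect_false(anyNA(cv$labels))
  # folds are mutually exclusive and exhaustive
  expect_setequal(cv$fold_of, 1:10)
  expect_length(cv$fold_of, nrow(Xb))
  # leave-one-out still recovers the blobs and matches the full fit
  cfg_loo <- search_config(n_bootstrap = 4L, n_folds = nrow(Xb), seed = 13)
  cv_loo <- cv_membership(Xb, pipeline_spec("M1"), list(kmeans.n_clusters = 2L),
                          cfg_loo)
  full <- fit_pipeline(pipeline_spec("M1", list(kmeans.n_clusters = 2L)), Xb,
                       seed = derive_seed(cfg_loo$seed, "reference"))
  expect_equal(adjusted_rand_index(cv_loo$labels, full$train_labels), 1)
})

test_that("fold labels are aligned to the reference by Hungarian matching", {
  ref <- c(1L, 1L, 2L, 2L, 3L, 3L)
  from <- c(3L, 3L, 1L, 1L, 2L, 2L)  # permuted version of ref
  expect_identical(stabpipe:::match_labels(from, ref), ref)
  # arbitrary permutations come back identical after matching
  withr::with_seed(17, for (i in 1:10) {
    lab <- sample(1:4, 40, TRUE)
    perm <- sample(1:4)
    expect_identical(stabpipe:::match_labels(perm[lab], lab), lab)
  })
  # surplus clusters in `from` get fresh labels beyond the reference's
  from2 <- c(1L, 2L, 3L, 3L)
  ref2 <- c(1L, 2L, 2L, 2L)
  out <- stabpipe:::match_labels(from2, ref2)
  expect_equal(length(unique(out)), 3L)
})

test_that("stability does not decrease with cluster separation (M4 smoke test)", {
  ref <- iris_reference()
  med_ari <- vapply(c("small", "large"), function(lvl) {
    p <- derive_mixture_params(ref, lvl)
    aris <- vapply(1:3, function(s) {
      ds <- simulate_dataset(p, sim_config(lvl, 250, 4, seed = 100 + s))
      X <- apply_preprocess(fit_preprocess(ds$features), ds$features)
      cfg <- search_config(n_bootstrap = 6L, seed = 200 + s)
      score_combo(X, pipeline_spec("M4"),
                  list(nmf.n_components = 2L, kmeans.n_clusters = 2L),
                  cfg)$mean_ari
    }, numeric(1))
    stats::median(aris)
  }, numeric(1))
  expect_lte(med_ari[["small"]], med_ari[["large"]] + 1e-9)
})
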