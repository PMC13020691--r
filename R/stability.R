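# Bootstrap consecutive-pair ARI stability search: grid search over
# hyperparameter combinations scored by (i) the mean adjusted Rand index
# between the full-dataset cluster assignments of consecutive bootstrap
# fits and (ii) the mean Davies-Bouldin index across bootstraps, followed
# by the two-stage top-ARI / minimum-DBI selection rule and a final 10-fold
# cross-validated cluster membership.

#' Search configuration
#'
#' @param n_bootstrap Number of bootstrap resamples (the stability
#'   statistic averages over the `n_bootstrap - 1` consecutive pairs).
#' @param bootstrap_fraction Fraction of observations drawn per resample
#'   (default 0.9).
#' @param sample_with_replacement Draw with replacement (default `TRUE`).
#' @param n_folds Folds for the final cross-validated membership.
#' @param top_k_ari Size of the ARI short-list the minimum-DBI rule picks
#'   from (default 5).
#' @param seed Master seed; per-combination and per-bootstrap seeds are
#'   derived from it deterministically.
#' @param control A [pipeline_control()] list passed to every fit.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_bootstrap = 100L, bootstrap_fraction = 0.9,
                          sample_with_replacement = TRUE, n_folds = 10L,
                          top_k_ari = 5L, seed = 1L,
                          control = pipeline_control()) {
  stopifnot(n_bootstrap >= 2L, bootstrap_fraction > 0, bootstrap_fraction <= 1,
            n_folds >= 2L, top_k_ari >= 1L)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 bootstrap_fraction = bootstrap_fraction,
                 sample_with_replacement = isTRUE(sample_with_replacement),
                 n_folds = as.integer(n_folds),
                 top_k_ari = as.integer(top_k_ari),
                 seed = as.integer(seed), control = control),
            class = "search_config")
}

#' Bootstrap index vectors
#'
#' Draws `n_bootstrap` index vectors of length
#' `round(bootstrap_fraction * n)`, uniformly with (or without)
#' replacement from `1..n`; deterministic under `cfg$seed`.
#'
#' @param n Number of observations.
#' @param cfg A [search_config()].
#' @return List of integer vectors.
#' @export
bootstrap_indices <- function(n, cfg) {
  stopifnot(inherits(cfg, "search_config"), n >= 2L)
  m <- round(cfg$bootstrap_fraction * n)
  if (m < 2L) stop("bootstrap_fraction * n must be at least 2")
  withr::with_seed(cfg$seed, lapply(seq_len(cfg$n_bootstrap), function(b)
    sample.int(n, m, replace = cfg$sample_with_replacement)))
}

# quick static feasibility check before any fitting
combo_feasible <- function(spec, m_train, width) {
  cur <- width
  for (st in spec$stages) {
    hp <- st$hyperparams
    msg <- switch(st$kind,
      kernel_pca = if ((hp$n_components %||% 2L) > cur ||
                       (hp$n_components %||% 2L) >= m_train)
        sprintf("kernel_pca n_components = %s exceeds width %d", hp$n_components, cur),
      nmf = if ((hp$n_components %||% 5L) > min(cur, m_train))
        sprintf("nmf n_components = %s exceeds width %d", hp$n_components, cur),
      tsne = if (3 * (hp$perplexity %||% 30) >= m_train)
        sprintf("perplexity %s too large for %d observations", hp$perplexity, m_train),
      kmeans = ,
      spectral = if ((hp$n_clusters %||% 3L) > m_train)
        sprintf("n_clusters = %s exceeds sample size", hp$n_clusters)
    )
    if (!is.null(msg)) return(msg)
    cur <- switch(st$kind, kernel_pca = hp$n_components %||% 2L,
                  nmf = hp$n_components %||% 5L, tsne = 2L, cur)
  }
  NULL
}

new_stability_record <- function(combo, mean_ari = NA_real_,
                                 mean_dbi = NA_real_, n_valid_pairs = 0L,
                                 n_valid_boots = 0L, failure_flag = "") {
  structure(list(combo = combo, mean_ari = mean_ari, mean_dbi = mean_dbi,
                 n_valid_pairs = as.integer(n_valid_pairs),
                 n_valid_boots = as.integer(n_valid_boots),
                 failure_flag = failure_flag),
            class = "stability_record")
}

#' Score one hyperparameter combination by bootstrap stability
#'
#' For each bootstrap resample the pipeline is fitted on the resample and
#' used to assign cluster labels to the full dataset; the stability score
#' is the mean ARI between the full-dataset label vectors of consecutive
#' (valid) bootstraps, and the compactness score is the mean
#' Davies-Bouldin index of the full dataset in each bootstrap's reduced
#' space under that bootstrap's labels. Bootstraps whose fit degenerates
#' (error, single nonempty cluster, non-finite embedding) are excluded and
#' recorded in `failure_flag`; with fewer than two valid fits the ARI is
#' `NA`.
#'
#' @param data Preprocessed numeric matrix.
#' @param spec A `pipeline_spec`.
#' @param combo Named list of hyperparameter values
#'   (`<stage_kind>.<param>`), overriding the spec's.
#' @param cfg A [search_config()].
#' @return A `stability_record`.
#' @export
score_combo <- function(data, spec, combo, cfg) {
  stopifnot(inherits(spec, "pipeline_spec"), inherits(cfg, "search_config"))
  x <- stop_if_not_matrix(data, "data")
  spec <- pipeline_spec(spec$pipeline_id, combo)  # validates names
  idx <- bootstrap_indices(nrow(x), cfg)
  feas <- combo_feasible(spec, length(idx[[1L]]), ncol(x))
  if (!is.null(feas)) return(new_stability_record(combo, failure_flag = feas))

  labels_list <- vector("list", cfg$n_bootstrap)
  dbis <- rep(NA_real_, cfg$n_bootstrap)
  failures <- character(0)
  for (b in seq_len(cfg$n_bootstrap)) {
    res <- tryCatch({
      fp <- fit_pipeline(spec, x[idx[[b]], , drop = FALSE],
                         seed = derive_seed(cfg$seed, "boot", b),
                         control = cfg$control)
      ar <- assign_with_reduced(fp, x)
      if (length(unique(ar$labels)) < 2L) stop("single nonempty cluster")
      if (!all(is.finite(ar$reduced))) stop("non-finite embedding")
      ar
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("boot %d: %s", b, conditionMessage(res)))
    } else {
      labels_list[[b]] <- res$labels
      dbis[b] <- as.numeric(davies_bouldin(res$reduced, res$labels))
    }
  }
  valid <- which(!vapply(labels_list, is.null, logical(1)))
  flag <- paste(failures, collapse = "; ")
  if (length(valid) < 2L)
    return(new_stability_record(combo, n_valid_boots = length(valid),
                                failure_flag = if (nzchar(flag)) flag else
                                  "fewer than 2 valid bootstrap fits"))
  aris <- vapply(seq_len(length(valid) - 1L), function(i)
    adjusted_rand_index(labels_list[[valid[i]]], labels_list[[valid[i + 1L]]]),
    numeric(1))
  new_stability_record(combo,
                       mean_ari = mean(aris),
                       mean_dbi = mean(dbis[valid], na.rm = TRUE),
                       n_valid_pairs = length(aris),
                       n_valid_boots = length(valid),
                       failure_flag = flag)
}

#' Grid search over hyperparameter combinations
#'
#' Scores every combination of the Cartesian product of `grid` with
#' [score_combo()], in deterministic (lexicographic) order, using an
#' independent seed per combination derived from `cfg$seed` and the
#' combination index.
#'
#' @param data Preprocessed numeric matrix.
#' @param spec A `pipeline_spec`.
#' @param grid Named list of value vectors keyed `<stage_kind>.<param>`
#'   (see [default_grid()]).
#' @param cfg A [search_config()].
#' @return A list of `stability_record`s (class `stability_records`).
#' @export
grid_search <- function(data, spec, grid, cfg) {
  if (!length(grid)) stop("empty hyperparameter grid")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    combo <- as.list(combos[i, , drop = FALSE])
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, "combo", i)
    records[[i]] <- score_combo(data, spec, combo, cfg_i)
    records[[i]]$combo_index <- i
  }
  structure(records, class = "stability_records",
            pipeline_id = spec$pipeline_id)
}

#' @export
as.data.frame.stability_records <- function(x, ...) {
  data.frame(
    pipeline_id = attr(x, "pipeline_id") %||% NA_character_,
    combo_index = vapply(x, function(r) r$combo_index %||% NA_integer_, integer(1)),
    combo = vapply(x, function(r)
      as.character(jsonlite::toJSON(r$combo, auto_unbox = TRUE, digits = NA)),
      character(1)),
    mean_ari = vapply(x, function(r) r$mean_ari, numeric(1)),
    mean_dbi = vapply(x, function(r) r$mean_dbi, numeric(1)),
    n_valid_pairs = vapply(x, function(r) r$n_valid_pairs, integer(1)),
    failure_flag = vapply(x, function(r) r$failure_flag, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Two-stage hyperparameter selection: top ARI, then minimum DBI
#'
#' Ranks valid records by mean ARI (descending; ties broken by lower mean
#' DBI, then grid order), short-lists the top `cfg$top_k_ari`, and returns
#' the short-listed record with the lowest mean DBI (ties again by grid
#' order).
#'
#' @param records A `stability_records` list (or plain list of records).
#' @param cfg A [search_config()].
#' @return The selected `stability_record`.
#' @export
select_combo <- function(records, cfg) {
  stopifnot(inherits(cfg, "search_config"))
  ari <- vapply(records, function(r) r$mean_ari, numeric(1))
  dbi <- vapply(records, function(r) r$mean_dbi, numeric(1))
  valid <- which(!is.na(ari))
  if (!length(valid)) stop("no stable combination: all records are NA")
  ord <- valid[order(-ari[valid], ifelse(is.na(dbi[valid]), Inf, dbi[valid]),
                     valid)]
  short <- ord[seq_len(min(cfg$top_k_ari, length(ord)))]
  dbi_short <- ifelse(is.na(dbi[short]), Inf, dbi[short])
  sel <- short[order(dbi_short, short)][1L]
  records[[sel]]
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("stability_record: mean ARI %s, mean DBI %s (%d valid pairs)%s\n",
              format(x$mean_ari, digits = 4), format(x$mean_dbi, digits = 4),
              x$n_valid_pairs,
              if (nzchar(x$failure_flag)) paste0(" [", x$failure_flag, "]") else ""))
  invisible(x)
}

#' Cross-validated cluster membership
#'
#' Splits the data into `cfg$n_folds` mutually exclusive folds; for each
#' fold, fits the pipeline on the remaining folds and assigns the held-out
#' observations out of sample. Each fold model's labels are aligned to a
#' reference pipeline fitted once on all data by maximum-overlap
#' (Hungarian) matching on the shared training observations, so the
#' concatenated labels live in one label space.
#'
#' @param data Preprocessed numeric matrix.
#' @param spec A `pipeline_spec`.
#' @param combo Named hyperparameter list (typically the selected record's
#'   `combo`).
#' @param cfg A [search_config()].
#' @return An object of class `cluster_assignment`: `labels` (one per
#'   observation; `NA` where a fold fit degenerated), `fold_of`, `combo`,
#'   `flags`.
#' @export
cv_membership <- function(data, spec, combo, cfg) {
  stopifnot(inherits(spec, "pipeline_spec"), inherits(cfg, "search_config"))
  x <- stop_if_not_matrix(data, "data")
  spec <- pipeline_spec(spec$pipeline_id, combo)
  n <- nrow(x)
  fold_of <- withr::with_seed(derive_seed(cfg$seed, "folds"),
    sample(rep(seq_len(cfg$n_folds), length.out = n)))
  ref <- fit_pipeline(spec, x, seed = derive_seed(cfg$seed, "reference"),
                      control = cfg$control)
  ref_labels <- assign_out_of_sample(ref, x)
  labels <- rep(NA_integer_, n)
  flags <- character(0)
  for (f in seq_len(cfg$n_folds)) {
    test <- fold_of == f
    res <- tryCatch({
      fp <- fit_pipeline(spec, x[!test, , drop = FALSE],
                         seed = derive_seed(cfg$seed, "fold", f),
                         control = cfg$control)
      train_assigned <- fp$train_labels
      aligned <- match_labels(train_assigned, ref_labels[!test])
      held <- assign_out_of_sample(fp, x[test, , drop = FALSE])
      map_tab <- unique(data.frame(from = train_assigned, to = aligned))
      as.integer(map_tab$to[match(held, map_tab$from)])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, sprintf("fold %d: %s", f, conditionMessage(res)))
    } else {
      labels[test] <- res
    }
  }
  structure(list(labels = labels, fold_of = fold_of, combo = combo,
                 flags = flags),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d observations, %d clusters, %d folds%s\n",
              length(x$labels), length(unique(stats::na.omit(x$labels))),
              length(unique(x$fold_of)),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
              else ""))
  invisible(x)
}
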