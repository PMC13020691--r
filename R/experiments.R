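# End-to-end orchestration: the factorial simulation study
# (effect level x noise-covariate count x pipeline), application to a
# user-supplied feature table, and the effect-size reference report based
# on inter-pipeline concordance.

#' Study configuration
#'
#' @param effect_levels Subset of `c("small", "medium", "large")`.
#' @param noise_counts Subset of `c(0, 4, 20, 40, 60, 80, 140, 200)` (other
#'   nonnegative counts are accepted).
#' @param pipelines Subset of [pipeline_ids()].
#' @param search A [search_config()]; its `seed` is overridden per
#'   condition by seeds derived from `master_seed`.
#' @param grids Optional named list (by pipeline id) of hyperparameter
#'   grids; missing entries use [default_grid()].
#' @param n_obs Observations per simulated dataset (default 1000).
#' @param corr_threshold Correlation-filter threshold for preprocessing.
#' @param master_seed Master seed; per-condition seeds are derived by
#'   hashing `(master_seed, effect_level, noise_count, pipeline_id)` so
#'   conditions are order-independent.
#' @param output_dir Optional directory for tidy CSV/JSON outputs.
#' @return A list of class `study_config`.
#' @export
study_config <- function(effect_levels = c("small", "medium", "large"),
                         noise_counts = c(0L, 4L, 20L, 40L, 60L, 80L, 140L, 200L),
                         pipelines = pipeline_ids(),
                         search = search_config(),
                         grids = NULL, n_obs = 1000L, corr_threshold = 0.95,
                         master_seed = 1L, output_dir = NULL) {
  stopifnot(length(effect_levels) >= 1L, length(noise_counts) >= 1L,
            length(pipelines) >= 1L, all(pipelines %in% pipeline_ids()),
            all(effect_levels %in% names(EFFECT_TARGETS)))
  structure(list(effect_levels = effect_levels,
                 noise_counts = as.integer(noise_counts),
                 pipelines = pipelines, search = search, grids = grids,
                 n_obs = as.integer(n_obs), corr_threshold = corr_threshold,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "study_config")
}

# search+select+membership for one pipeline on a preprocessed matrix
run_one_pipeline <- function(X, pid, grid, scfg) {
  spec <- pipeline_spec(pid)
  records <- grid_search(X, spec, grid, scfg)
  sel <- tryCatch(select_combo(records, scfg), error = function(e) e)
  if (inherits(sel, "error")) {
    return(list(records = records, selected = NULL, membership = NULL,
                status = "not stable"))
  }
  cv <- cv_membership(X, spec, sel$combo, scfg)
  list(records = records, selected = sel, membership = cv, status = "ok")
}

#' Run the simulation study
#'
#' For every (effect level, noise count, pipeline) condition: simulate,
#' preprocess, run the bootstrap grid search, select hyperparameters by the
#' top-ARI / min-DBI rule, produce the 10-fold CV membership and score it
#' against the simulated ground truth with Cramer's V; per (effect, noise)
#' condition the inter-pipeline concordance matrix is also computed.
#' Pipeline failures become `"not stable"` rows, never errors. Fully
#' reproducible from `cfg$master_seed`.
#'
#' @param cfg A [study_config()].
#' @param ref Reference data for [derive_mixture_params()]; defaults to
#'   [iris_reference()].
#' @return A list of class `study_report`: `results` (tidy data frame, one
#'   row per condition x pipeline), `concordance` (named list of matrices),
#'   `memberships` (named list of per-pipeline label lists).
#' @export
run_simulation_study <- function(cfg, ref = iris_reference()) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list(); concordance <- list(); memberships <- list()
  for (effect in cfg$effect_levels) {
    params <- derive_mixture_params(ref, effect)
    for (noise in cfg$noise_counts) {
      cond <- sprintf("%s_noise%d", effect, noise)
      sim_seed <- derive_seed(cfg$master_seed, "sim", effect, noise)
      ds <- simulate_dataset(params, sim_config(effect, cfg$n_obs, noise,
                                                seed = sim_seed))
      prep <- fit_preprocess(ds$features, cfg$corr_threshold)
      X <- apply_preprocess(prep, ds$features)
      labels_by_pipeline <- list()
      for (pid in cfg$pipelines) {
        scfg <- cfg$search
        scfg$seed <- derive_seed(cfg$master_seed, effect, noise, pid)
        grid <- (cfg$grids[[pid]] %||% default_grid(pid))
        out <- run_one_pipeline(X, pid, grid, scfg)
        if (out$status == "ok") {
          lab <- out$membership$labels
          v <- as.numeric(cramers_v(lab, ds$ground_truth))
          rows[[length(rows) + 1L]] <- data.frame(
            effect_level = effect, n_noise = noise, pipeline_id = pid,
            status = "ok",
            mean_ari = out$selected$mean_ari,
            mean_dbi = out$selected$mean_dbi,
            combo = as.character(jsonlite::toJSON(out$selected$combo,
                                                  auto_unbox = TRUE, digits = NA)),
            n_clusters_detected = length(unique(stats::na.omit(lab))),
            ground_truth_v = v, stringsAsFactors = FALSE)
          labels_by_pipeline[[pid]] <- lab
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            effect_level = effect, n_noise = noise, pipeline_id = pid,
            status = "not stable", mean_ari = NA_real_, mean_dbi = NA_real_,
            combo = NA_character_, n_clusters_detected = NA_integer_,
            ground_truth_v = NA_real_, stringsAsFactors = FALSE)
          labels_by_pipeline[[pid]] <- rep(NA_integer_, nrow(X))
        }
      }
      if (length(labels_by_pipeline) >= 2L)
        concordance[[cond]] <- concordance_matrix(labels_by_pipeline)
      memberships[[cond]] <- labels_by_pipeline
    }
  }
  report <- structure(list(results = do.call(rbind, rows),
                           concordance = concordance,
                           memberships = memberships, config = cfg),
                      class = "study_report")
  if (!is.null(cfg$output_dir)) write_study_report(report, cfg$output_dir)
  report
}

write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$results, file.path(dir, "study_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(report$concordance, function(m)
      list(pipelines = rownames(m), v = m)),
    file.path(dir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Apply the full search to a user feature table
#'
#' Reads a delimited feature table (header row, observation-id first
#' column), optionally a table of binary outcome columns, preprocesses,
#' optimizes each requested pipeline with the bootstrap search and reports
#' robustness (selected mean ARI), decision-tree interpretability accuracy,
#' per-outcome logistic AUROC and the inter-pipeline concordance matrix.
#' Unstable pipelines are reported as `"not stable"` rows.
#'
#' @param features_path CSV path: `obs_id` column first, numeric features.
#' @param outcomes_path Optional CSV path: `obs_id` plus binary outcome
#'   columns (same observations, same order not required).
#' @param cfg A [study_config()] (its `effect_levels`/`noise_counts` are
#'   ignored here).
#' @param outcome_names Optional subset of outcome columns to evaluate; an
#'   absent requested column is an error naming it.
#' @return A list of class `application_report`: `results` (one row per
#'   pipeline), `concordance`, `memberships`.
#' @export
run_data_application <- function(features_path, outcomes_path = NULL,
                                 cfg = study_config(), outcome_names = NULL) {
  df <- utils::read.csv(features_path, check.names = FALSE)
  if (!"obs_id" %in% names(df)) {
    names(df)[1L] <- "obs_id"
  }
  drop_cols <- c("obs_id", "ground_truth")
  feats <- as.matrix(df[, setdiff(names(df), drop_cols), drop = FALSE])
  outcomes <- NULL
  if (!is.null(outcomes_path)) {
    odf <- utils::read.csv(outcomes_path, check.names = FALSE)
    if (!"obs_id" %in% names(odf)) names(odf)[1L] <- "obs_id"
    odf <- odf[match(df$obs_id, odf$obs_id), , drop = FALSE]
    outcomes <- odf[, setdiff(names(odf), "obs_id"), drop = FALSE]
  }
  if (!is.null(outcome_names)) {
    missing <- setdiff(outcome_names, colnames(outcomes))
    if (length(missing))
      stop(sprintf("outcome column '%s' not found", missing[1L]))
    outcomes <- outcomes[, outcome_names, drop = FALSE]
  }
  prep <- fit_preprocess(feats, cfg$corr_threshold)
  X <- apply_preprocess(prep, feats)
  rows <- list(); labels_by_pipeline <- list()
  outcome_cols <- if (is.null(outcomes)) character(0) else colnames(outcomes)
  for (pid in cfg$pipelines) {
    scfg <- cfg$search
    scfg$seed <- derive_seed(cfg$master_seed, "apply", pid)
    grid <- (cfg$grids[[pid]] %||% default_grid(pid))
    out <- run_one_pipeline(X, pid, grid, scfg)
    if (out$status == "ok") {
      lab <- out$membership$labels
      row <- data.frame(pipeline_id = pid, status = "ok",
                        robustness = out$selected$mean_ari,
                        interpretability = interpretability_accuracy(
                          X, lab, list(seed = derive_seed(cfg$master_seed,
                                                          "cart", pid))),
                        n_clusters_detected = length(unique(stats::na.omit(lab))),
                        stringsAsFactors = FALSE)
      for (oc in outcome_cols)
        row[[paste0("auroc_", oc)]] <- outcome_association(lab, outcomes[[oc]])
      labels_by_pipeline[[pid]] <- lab
    } else {
      row <- data.frame(pipeline_id = pid, status = "not stable",
                        robustness = NA_real_, interpretability = NA_real_,
                        n_clusters_detected = NA_integer_,
                        stringsAsFactors = FALSE)
      for (oc in outcome_cols) row[[paste0("auroc_", oc)]] <- NA_real_
      labels_by_pipeline[[pid]] <- rep(NA_integer_, nrow(X))
    }
    rows[[length(rows) + 1L]] <- row
  }
  structure(list(results = do.call(rbind, rows),
                 concordance = if (length(labels_by_pipeline) >= 2L)
                   concordance_matrix(labels_by_pipeline) else NULL,
                 memberships = labels_by_pipeline, config = cfg),
            class = "application_report")
}

#' Effect-size reference report from inter-pipeline concordance
#'
#' Summarizes the distribution of off-diagonal inter-pipeline Cramer's V
#' values and classifies the implied latent clustering effect: most values
#' below 0.3 suggest a weak structure, most within 0.3-0.7 a moderate one
#' worth exploring, most above 0.7 a strong one.
#'
#' @param report A `study_report`, `application_report`, or a single
#'   concordance matrix.
#' @return A data frame with one row per concordance matrix: counts per
#'   band, median V and the classification (`weak` / `moderate` /
#'   `strong`, or `NA` with fewer than 2 successful pipelines).
#' @export
effectsize_reference_report <- function(report) {
  mats <- if (is.matrix(report)) list(overall = report)
          else if (inherits(report, "application_report"))
            list(overall = report$concordance)
          else report$concordance
  rows <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    v <- m[upper.tri(m)]
    v <- v[!is.na(v)]
    if (length(v) < 1L)
      return(data.frame(condition = nm, n_pairs = 0L, n_weak = NA_integer_,
                        n_moderate = NA_integer_, n_strong = NA_integer_,
                        median_v = NA_real_, classification = NA_character_,
                        stringsAsFactors = FALSE))
    bands <- c(weak = sum(v < 0.3), moderate = sum(v >= 0.3 & v <= 0.7),
               strong = sum(v > 0.7))
    cls <- if (bands["weak"] > length(v) / 2) "weak"
           else if (bands["strong"] > length(v) / 2) "strong"
           else if (bands["moderate"] > length(v) / 2) "moderate"
           else names(bands)[which.max(bands)]
    data.frame(condition = nm, n_pairs = length(v),
               n_weak = unname(bands["weak"]),
               n_moderate = unname(bands["moderate"]),
               n_strong = unname(bands["strong"]),
               median_v = stats::median(v), classification = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
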