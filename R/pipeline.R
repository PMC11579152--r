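#' Pipeline configuration
#'
#' Collects every choice of a full run: input source (simulate, or paths to
#' the two CSVs), theta standardisation, HMM state count, classifier list,
#' trials, dataset variants, explanation settings and the single master
#' seed from which all randomness is derived.
#'
#' @param simulate Generate a synthetic cohort instead of reading files?
#' @param theta_csv,coords_csv Input paths when `simulate = FALSE`.
#' @param n_per_group Cohort size per group when simulating.
#' @param scale Theta standardisation: `"raw"`, `"minmax"` or `"zscore"`.
#' @param M HMM state count.
#' @param classifiers Character vector of classifier names (see
#'   [classifier_spec()]).
#' @param trials Trials to evaluate.
#' @param datasets Dataset variants to evaluate.
#' @param explain_classifier Classifier explained on the combined table
#'   (`NULL` to skip the explanation stage).
#' @param K Features retained per subject by the explainer.
#' @param lmm_per_fold Refit the peak mixed model inside each LOOCV
#'   training fold (leakage-free)? `FALSE` gives the fit-once protocol.
#' @param include_duration Include series duration in the EEG features.
#' @param include_summaries Also add the per-series mean and SD as EEG
#'   features (off by default).
#' @param eps Idle-time displacement tolerance (Vm).
#' @param seed Master integer seed.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @param cols Column mapping for the readers, see [theta_cols()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, theta_csv = NULL, coords_csv = NULL,
                            n_per_group = 25, scale = "zscore", M = 4,
                            classifiers = names(default_classifiers()),
                            trials = c(1, 12),
                            datasets = c("eeg", "coordinates", "combined"),
                            explain_classifier = "dnn", K = 3,
                            lmm_per_fold = TRUE, include_duration = TRUE,
                            include_summaries = FALSE,
                            eps = 0, seed = 1L, out_dir = NULL,
                            cols = theta_cols()) {
  known <- names(default_classifiers())
  bad <- setdiff(classifiers, known)
  if (length(bad) > 0) {
    abort(sprintf("unknown classifier name(s): %s", paste(bad, collapse = ", ")),
          class = "thetanav_config_error")
  }
  if (!is.null(explain_classifier) && !explain_classifier %in% known) {
    abort(sprintf("unknown classifier name: %s", explain_classifier),
          class = "thetanav_config_error")
  }
  scale <- match.arg(scale, c("raw", "minmax", "zscore"))
  datasets <- match.arg(datasets, c("eeg", "coordinates", "combined"),
                        several.ok = TRUE)
  structure(list(simulate = simulate, theta_csv = theta_csv,
                 coords_csv = coords_csv, n_per_group = n_per_group,
                 scale = scale, M = M, classifiers = classifiers,
                 trials = as.integer(trials), datasets = datasets,
                 explain_classifier = explain_classifier, K = K,
                 lmm_per_fold = lmm_per_fold,
                 include_duration = include_duration,
                 include_summaries = include_summaries, eps = eps,
                 seed = as.integer(seed), out_dir = out_dir, cols = cols),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full feature-engineering and classification pipeline
#'
#' Stages: acquire data (simulate or read), standardise theta per series,
#' extract HMM and LMM features and the four trajectory features, assemble
#' the requested feature tables, evaluate every configured classifier under
#' LOOCV, and (optionally) explain one classifier's predictions on the
#' combined table. Deterministic given `config$seed`; one log line per
#' stage. When `config$out_dir` is set, feature tables, the AUROC report,
#' ROC points and explanation rankings are written as CSV (plus the
#' generating truth as JSON for simulated cohorts).
#'
#' @param config A [pipeline_config()].
#' @return A list: `report` (tibble of AUROCs per trial, dataset and
#'   classifier), `features` (named list of feature tables), `evals`
#'   (the `loocv_eval` objects), `explanations`, `top_features`, and the
#'   input `data`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (isTRUE(config$simulate)) {
    cohort <- simulate_cohort(cohort_spec(n_per_group = config$n_per_group,
                                          seed = sub_seed(seed, "simulation")))
    theta <- cohort$theta; coords <- cohort$coords; truth <- cohort$truth
  } else {
    if (is.null(config$theta_csv) || is.null(config$coords_csv)) {
      abort("theta_csv and coords_csv are required when simulate = FALSE",
            class = "thetanav_config_error")
    }
    theta <- read_theta_csv(config$theta_csv, config$cols)
    coords <- read_coordinates_csv(config$coords_csv, config$cols)
    truth <- NULL
  }
  theta_s <- standardise_theta(theta, config$scale)
  hmm_feats <- hmm_feature_table(theta_s, M = config$M,
                                 seed = sub_seed(seed, "hmm"))
  peaks <- peak_table(theta_s)
  lmm_feats <- lmm_feature_table(theta_s)
  traj_feats <- trajectory_features(coords, eps = config$eps)
  durs <- series_durations(theta_s)
  summ <- if (isTRUE(config$include_summaries)) series_summaries(theta_s) else NULL
  specs <- lapply(setNames(config$classifiers, config$classifiers), classifier_spec)
  tables <- list(); evals <- list()
  for (trial in config$trials) {
    for (ds in config$datasets) {
      tab <- assemble_feature_table(hmm_feats, lmm_feats, traj_feats,
                                    variant = ds, trial = trial,
                                    durations = durs,
                                    include_duration = config$include_duration,
                                    summaries = summ,
                                    scale = config$scale)
      tables[[paste0(ds, "_trial", trial)]] <- tab
      trial_peaks <- dplyr::filter(peaks, .data$trial == !!trial)
      for (cl in config$classifiers) {
        ev <- loocv_evaluate(tab, specs[[cl]],
                             seed = sub_seed(seed, paste0("eval-", ds, "-", trial, "-", cl)),
                             peaks = if (ds != "coordinates" && config$lmm_per_fold)
                               trial_peaks else NULL)
        evals[[paste(ds, trial, cl, sep = "_")]] <- ev
      }
    }
  }
  report <- dplyr::bind_rows(purrr::map(evals, glance))
  explanations <- NULL; top_features <- NULL
  if (!is.null(config$explain_classifier) && "combined" %in% config$datasets) {
    ex <- purrr::map(config$trials, function(trial) {
      tab <- tables[[paste0("combined_trial", trial)]]
      X <- feature_matrix(tab)
      model <- train_classifier(specs[[config$explain_classifier]] %||%
                                  classifier_spec(config$explain_classifier),
                                X, tab$label,
                                seed = sub_seed(seed, paste0("explain-fit-", trial)))
      explain_subjects(model, tab, K = config$K,
                       seed = sub_seed(seed, paste0("explain-", trial)))
    })
    explanations <- dplyr::bind_rows(ex)
    top_features <- top_frequent_features(explanations, k = config$K)
  }
  result <- list(report = report, features = tables, evals = evals,
                 explanations = explanations, top_features = top_features,
                 data = list(theta = theta, coords = coords, truth = truth),
                 config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$report, file.path(out_dir, "auroc_report.csv"))
  for (nm in names(result$features)) {
    readr::write_csv(as_tibble(result$features[[nm]]),
                     file.path(out_dir, paste0("features_", nm, ".csv")))
  }
  roc <- purrr::imap(result$evals, function(ev, nm) {
    dplyr::mutate(roc_points(ev$scores$score, ev$scores$label), eval = nm)
  })
  readr::write_csv(dplyr::bind_rows(roc), file.path(out_dir, "roc_points.csv"))
  if (!is.null(result$explanations)) {
    readr::write_csv(as_tibble(result$explanations),
                     file.path(out_dir, "explanations.csv"))
    readr::write_csv(result$top_features, file.path(out_dir, "top_features.csv"))
  }
  if (!is.null(result$data$truth)) {
    truth <- result$data$truth
    truth$spec <- unclass(truth$spec)
    truth$spec$hmm_truth <- lapply(truth$spec$hmm_truth,
                                   function(g) lapply(g, unclass))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_stage("outputs written to %s", out_dir)
  invisible(out_dir)
}

#' ROC curve points from scores and labels
#'
#' @param scores Continuous scores.
#' @param labels Binary 0/1 labels.
#' @return Tibble of (`fpr`, `tpr`, `threshold`) stepping through the
#'   distinct score thresholds.
#' @export
roc_points <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tibble(threshold = th,
         tpr = vapply(th, function(t) mean(scores[labels == 1] >= t), 1),
         fpr = vapply(th, function(t) mean(scores[labels == 0] >= t), 1))
}
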