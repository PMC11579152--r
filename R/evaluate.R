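#' Area under the ROC curve
#'
#' Mann-Whitney construction: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting one
#' half. Computed from midranks, so it is exact and invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Binary 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)) # 1
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC is undefined with a single class", class = "thetanav_metric_error")
  }
  r <- rank(scores) # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Series durations per subject and trial
#'
#' The recorded epoch length of each theta series (last minus first time
#' stamp), used as the extra "time series feature" of the EEG dataset:
#' learner trials end when the goal is found, so duration carries
#' behavioural signal.
#'
#' @param theta A `theta_df` tibble.
#' @return Tibble with columns `subject`, `trial`, `duration`.
#' @export
series_durations <- function(theta) {
  theta |>
    dplyr::summarise(duration = max(.data$time) - min(.data$time),
                     .by = c("subject", "trial"))
}

#' Basic per-series summaries (optional extra EEG features)
#' @param theta A `theta_df` tibble.
#' @return Tibble with columns `subject`, `trial`, `series_mean`, `series_sd`.
#' @export
series_summaries <- function(theta) {
  theta |>
    dplyr::summarise(series_mean = mean(.data$theta), series_sd = sd(.data$theta),
                     .by = c("subject", "trial"))
}

#' Assemble a subjects-by-features classification table
#'
#' Joins the feature families into the unit of classification: one row per
#' subject for one trial, with a binary label (learner = 1, non-learner =
#' 0). The `eeg` variant carries the HMM and LMM features plus the series
#' duration; the `coordinates` variant the four trajectory features; and
#' `combined` their union (the variant used for the explanation analysis).
#'
#' @param hmm_feats Output of [hmm_feature_table()] (or `NULL` for the
#'   coordinates variant).
#' @param lmm_feats Output of [lmm_feature_table()] (or `NULL`).
#' @param traj_feats Output of [trajectory_features()] (or `NULL` for the
#'   eeg variant).
#' @param variant Dataset tag: `"eeg"`, `"coordinates"` or `"combined"`.
#' @param trial Which trial's rows to keep (1 or 12).
#' @param durations Optional [series_durations()] tibble; required for the
#'   eeg/combined variants unless `include_duration = FALSE`.
#' @param summaries Optional [series_summaries()] tibble; when supplied, the
#'   per-series mean and SD join the eeg/combined variants as extra
#'   time-series features.
#' @param include_duration Include the series-duration column in the
#'   eeg/combined variants?
#' @param scale Standardisation tag recorded on the table.
#' @return A tibble of class `feature_table`: `subject`, `group`, `trial`,
#'   `label` and feature columns; attributes `dataset` and `scale`.
#' @export
assemble_feature_table <- function(hmm_feats = NULL, lmm_feats = NULL,
                                   traj_feats = NULL,
                                   variant = c("eeg", "coordinates", "combined"),
                                   trial = 12, durations = NULL,
                                   include_duration = TRUE, summaries = NULL,
                                   scale = "raw") {
  variant <- match.arg(variant)
  trial <- as.integer(trial)
  pick_trial <- function(df) {
    df <- dplyr::filter(as_tibble(df), .data$trial == !!trial)
    dplyr::select(df, -dplyr::any_of(c("loglik", "aic", "n_iter", "converged",
                                       "n_peaks")))
  }
  parts <- list()
  if (variant %in% c("eeg", "combined")) {
    stopifnot(!is.null(hmm_feats), !is.null(lmm_feats))
    parts$hmm <- pick_trial(hmm_feats)
    parts$lmm <- pick_trial(lmm_feats)
    if (include_duration) {
      stopifnot(!is.null(durations))
      parts$dur <- pick_trial(durations)
    }
    if (!is.null(summaries)) parts$summ <- pick_trial(summaries)
  }
  if (variant %in% c("coordinates", "combined")) {
    stopifnot(!is.null(traj_feats))
    parts$traj <- pick_trial(traj_feats)
  }
  subjects <- lapply(parts, function(p) sort(unique(p$subject)))
  all_subj <- sort(unique(unlist(subjects)))
  missing <- lapply(subjects, function(s) setdiff(all_subj, s))
  if (any(lengths(missing) > 0)) {
    bad <- unique(unlist(missing))
    abort(sprintf("subject(s) missing from a feature source: %s",
                  paste(bad, collapse = ", ")), class = "thetanav_assembly_error")
  }
  out <- purrr::reduce(parts, function(a, b) {
    dplyr::left_join(a, dplyr::select(b, -dplyr::any_of(c("group", "trial"))),
                     by = "subject")
  })
  if (anyNA(out)) {
    abort("assembled feature table contains missing cells",
          class = "thetanav_assembly_error")
  }
  out <- out |>
    dplyr::mutate(label = as.integer(.data$group == "learner"),
                  .after = "trial") |>
    dplyr::relocate("subject", "group", "trial", "label")
  attr(out, "dataset") <- variant
  attr(out, "scale") <- scale
  class(out) <- c("feature_table", class(out))
  log_stage("feature table [%s, trial %d, %s]: %d subjects x %d features",
            variant, trial, scale, nrow(out), ncol(out) - 4)
  out
}

feature_matrix <- function(table) {
  meta <- c("subject", "group", "trial", "label", "scale", "dataset")
  f <- as.matrix(as_tibble(table)[setdiff(names(table), meta)])
  storage.mode(f) <- "double"
  rownames(f) <- table$subject
  f
}

scale_fold <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, s, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, s, "/"))
}

#' Leave-one-out cross-validated evaluation of one classifier
#'
#' Holds out each subject in turn, trains on the remaining `n - 1`, and
#' scores the held-out subject with a continuous score; the AUROC is
#' computed once over the `n` pooled held-out scores. Feature
#' standardisation (centre/scale by training-fold statistics) is applied
#' inside each fold for scale-sensitive learners (everything except the
#' random forest).
#'
#' When a peak table is supplied, the peak mixed model is refitted inside
#' every training fold and the held-out subject's intercept/slope are
#' predicted from the trained fixed effects and variances via
#' [predict_blups()] — the leakage-free protocol. `lmm_mode = "fit_once"`
#' keeps the LMM feature columns of `table` as given (a single fit on all
#' subjects).
#'
#' @param table A `feature_table` from [assemble_feature_table()].
#' @param spec A [classifier_spec()].
#' @param seed Master seed; each fold trains from its own substream.
#' @param peaks Optional peak tibble (all subjects, the table's trial) for
#'   the per-fold LMM mode.
#' @param lmm_mode `"per_fold"` (default when `peaks` is given) or
#'   `"fit_once"`.
#' @param reml Passed to [fit_peak_lmm()] in per-fold mode.
#' @param center_scores Centre each held-out score by the trained model's
#'   mean score over its own training fold (default `TRUE`). Pooling raw
#'   scores across leave-one-out folds is pessimistically biased: the
#'   training fold is missing exactly one subject of the held-out class, so
#'   every fold's score distribution shifts slightly against that class;
#'   removing the per-fold mean cancels this model-level shift while
#'   leaving the subject-level signal. Not applied to the 1-NN vote, whose
#'   score has no model-level scale to calibrate.
#' @return An object of class `loocv_eval`: per-subject held-out `scores`
#'   tibble, pooled `auroc`, classifier name and seed.
#' @export
loocv_evaluate <- function(table, spec, seed = 1L, peaks = NULL,
                           lmm_mode = c("per_fold", "fit_once"), reml = FALSE,
                           center_scores = TRUE) {
  lmm_mode <- match.arg(lmm_mode)
  stopifnot(inherits(spec, "classifier_spec"))
  n <- nrow(table)
  if (n < 4 || length(unique(table$label)) < 2) {
    abort("LOOCV needs >= 4 subjects with both classes present",
          class = "thetanav_validation_error")
  }
  per_fold_lmm <- !is.null(peaks) && lmm_mode == "per_fold" &&
    all(c("lmm_intercept", "lmm_slope") %in% names(table))
  if (per_fold_lmm) {
    peaks <- dplyr::filter(as_tibble(peaks), .data$subject %in% table$subject)
  }
  X <- feature_matrix(table)
  y <- table$label
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      warn(sprintf("fold %d skipped: single-class training fold", i))
      next
    }
    Xtr <- X[-i, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (per_fold_lmm) {
      fold_fit <- fit_peak_lmm(dplyr::filter(peaks, .data$subject %in% rownames(Xtr)),
                               reml = reml)
      blup_tr <- fold_fit$per_subject
      Xtr[, "lmm_intercept"] <- blup_tr$lmm_intercept[match(rownames(Xtr), blup_tr$subject)]
      Xtr[, "lmm_slope"] <- blup_tr$lmm_slope[match(rownames(Xtr), blup_tr$subject)]
      held_peaks <- dplyr::filter(peaks, .data$subject == table$subject[i])
      if (nrow(held_peaks) > 0) {
        blup_te <- predict_blups(fold_fit, held_peaks)
        Xte[, "lmm_intercept"] <- blup_te$lmm_intercept
        Xte[, "lmm_slope"] <- blup_te$lmm_slope
      } else {
        Xte[, "lmm_intercept"] <- fold_fit$beta0
        Xte[, "lmm_slope"] <- fold_fit$beta1
      }
    }
    if (spec$scale_sensitive) {
      sc <- scale_fold(Xtr, Xte)
      Xtr <- sc$train; Xte <- sc$test
    }
    model <- train_classifier(spec, Xtr, ytr, seed = sub_seed(seed, paste0("fold-", i)))
    s_i <- score_classifier(model, Xte)
    # 1-NN votes are a pure function of the fixed training geometry, with no
    # model-level score scale to calibrate; centring them would inject a
    # label-dependent offset instead of removing one
    if (center_scores && spec$name != "knn") {
      s_i <- s_i - mean(score_classifier(model, Xtr))
    }
    scores[i] <- s_i
  }
  keep <- !is.na(scores)
  structure(list(
    scores = tibble(subject = table$subject, label = y, score = scores),
    auroc = auroc(scores[keep], y[keep]),
    classifier = spec$name, n = n, seed = seed,
    dataset = attr(table, "dataset"), scale = attr(table, "scale"),
    trial = table$trial[1], lmm_mode = if (per_fold_lmm) "per_fold" else "fit_once"
  ), class = "loocv_eval")
}

#' @export
#' @method print loocv_eval
print.loocv_eval <- function(x, ...) {
  cat(sprintf("LOOCV %s [%s, trial %s, %s]: AUROC %.3f over %d subjects\n",
              x$classifier, x$dataset %||% "?", x$trial, x$scale %||% "?",
              x$auroc, x$n))
  invisible(x)
}

#' @export
tidy.loocv_eval <- function(x, ...) x$scores

#' @export
glance.loocv_eval <- function(x, ...) {
  tibble(classifier = x$classifier, dataset = x$dataset %||% NA_character_,
         trial = x$trial, scale = x$scale %||% NA_character_,
         auroc = x$auroc, n = x$n, lmm_mode = x$lmm_mode)
}

#' Evaluate several classifiers on one feature table
#'
#' @param table A `feature_table`.
#' @param classifiers List of [classifier_spec()] objects (default: all six).
#' @param ... Passed to [loocv_evaluate()].
#' @return A tibble with one row per classifier (AUROC and metadata).
#' @export
evaluate_all <- function(table, classifiers = default_classifiers(), ...) {
  purrr::map(classifiers, function(sp) glance(loocv_evaluate(table, sp, ...))) |>
    dplyr::bind_rows()
}
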