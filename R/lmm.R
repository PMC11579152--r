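#' Fit the peak-height mixed model
#'
#' Fits a linear mixed model of peak heights on peak curvatures with
#' independent per-subject random intercepts and random slopes (diagonal
#' random-effects covariance, i.e. `Corr(b0, b1) = 0`):
#'
#' \deqn{y_{ij} = b_{0i} + b_{1i} x_{ij} + e_{ij},\quad
#'       b_{0i} \sim N(\beta_0, \sigma_0^2),\;
#'       b_{1i} \sim N(\beta_1, \sigma_1^2),\;
#'       e_{ij} \sim N(0, \sigma^2)}
#'
#' where `y_ij` is the j-th peak height and `x_ij` the j-th peak curvature
#' of subject i. The per-subject predicted intercepts and slopes (BLUPs,
#' i.e. conditional means of the random effects given the data) are the two
#' features this model contributes to classification.
#'
#' Estimation uses `lme4::lmer` with the formula
#' `height ~ curvature + (1 | subject) + (0 + curvature | subject)`,
#' maximum likelihood by default. Subjects with fewer than 2 peaks are kept
#' (shrinkage still yields a prediction) but flagged in the log.
#'
#' @param peaks A peak tibble from [peak_table()] (columns `subject`,
#'   `height`, `curvature`; extra columns ignored).
#' @param reml Use REML instead of ML? Default `FALSE` (ML).
#' @return An object of class `peak_lmm` with elements `beta0`, `beta1`,
#'   `sigma2`, `sigma2_0`, `sigma2_1`, `loglik`, `per_subject` (tibble of
#'   BLUPs) and the underlying `lmerMod` in `model`.
#' @export
fit_peak_lmm <- function(peaks, reml = FALSE) {
  peaks <- as_tibble(peaks)
  stopifnot(all(c("subject", "height", "curvature") %in% names(peaks)))
  if (nrow(peaks) < 5) {
    abort("too few peaks to fit the mixed model (need >= 5 in total)",
          class = "thetanav_fit_error")
  }
  counts <- dplyr::count(peaks, .data$subject)
  if (nrow(counts) < 2) {
    abort("need at least 2 subjects to fit the mixed model",
          class = "thetanav_fit_error")
  }
  few <- counts$subject[counts$n < 2]
  if (length(few) > 0) {
    log_stage("peak LMM: %d subject(s) with < 2 peaks (BLUPs rely on shrinkage)",
              length(few))
  }
  dat <- data.frame(subject = factor(peaks$subject),
                    height = peaks$height, curvature = peaks$curvature)
  model <- suppressMessages(lme4::lmer(
    height ~ curvature + (1 | subject) + (0 + curvature | subject),
    data = dat, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fe <- lme4::fixef(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  sigma2_0 <- vc$vcov[vc$grp == "subject" & vc$var1 == "(Intercept)"]
  sigma2_1 <- vc$vcov[vc$grp == "subject.1" & vc$var1 == "curvature"]
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  fit <- structure(list(
    beta0 = unname(fe["(Intercept)"]), beta1 = unname(fe["curvature"]),
    sigma2 = sigma2, sigma2_0 = sigma2_0, sigma2_1 = sigma2_1,
    loglik = as.numeric(logLik(model)), reml = reml,
    n_peaks = nrow(dat), n_subjects = nrow(counts), model = model
  ), class = "peak_lmm")
  fit$per_subject <- predict_blups(fit, peaks)
  log_stage("peak LMM: %d subjects, %d peaks, logLik %.3f",
            fit$n_subjects, fit$n_peaks, fit$loglik)
  fit
}

#' Predicted per-subject intercepts and slopes (BLUPs)
#'
#' Computes the conditional mean of each subject's `(b0, b1)` given that
#' subject's peaks and the model's estimated fixed effects and variance
#' components:
#' `b_i = beta + D Z_i' (Z_i D Z_i' + sigma^2 I)^{-1} (y_i - Z_i beta)`
#' with `Z_i = [1, x_i]` and `D = diag(sigma2_0, sigma2_1)`. This closed
#' form works identically for training subjects and for a held-out subject
#' never seen by the fit, which is what the leakage-free cross-validation
#' mode uses. A subject with no peaks receives the population values
#' `(beta0, beta1)`.
#'
#' @param fit A `peak_lmm` object.
#' @param peaks Peak tibble for the subjects to predict (columns `subject`,
#'   `height`, `curvature`).
#' @return A tibble with columns `subject`, `lmm_intercept`, `lmm_slope`,
#'   `n_peaks`.
#' @export
predict_blups <- function(fit, peaks) {
  peaks <- as_tibble(peaks)
  D <- diag(c(fit$sigma2_0, fit$sigma2_1))
  beta <- c(fit$beta0, fit$beta1)
  peaks |>
    dplyr::summarise(
      {
        Z <- cbind(1, .data$curvature)
        r <- .data$height - as.numeric(Z %*% beta)
        V <- Z %*% D %*% t(Z) + fit$sigma2 * diag(length(r))
        u <- as.numeric(D %*% t(Z) %*% solve(V, r))
        tibble(lmm_intercept = beta[1] + u[1], lmm_slope = beta[2] + u[2],
               n_peaks = length(r))
      },
      .by = "subject"
    )
}

#' Per-subject LMM features
#'
#' Extracts the `lmm_intercept` and `lmm_slope` feature pair per subject
#' from a fitted peak model.
#'
#' @param fit A `peak_lmm` object.
#' @return Tibble with columns `subject`, `lmm_intercept`, `lmm_slope`.
#' @export
lmm_features <- function(fit) {
  fit$per_subject[c("subject", "lmm_intercept", "lmm_slope")]
}

#' LMM features for every trial of a cohort
#'
#' Detects peaks per series and fits one peak model per trial (both groups
#' pooled, since classification is evaluated per trial), returning the
#' per-subject intercept/slope features.
#'
#' @param theta A (standardised) `theta_df` tibble.
#' @param reml Passed to [fit_peak_lmm()].
#' @return Tibble with columns `subject`, `group`, `trial`, `lmm_intercept`,
#'   `lmm_slope`.
#' @export
lmm_feature_table <- function(theta, reml = FALSE) {
  peaks <- peak_table(theta)
  keys <- dplyr::distinct(as_tibble(theta), .data$subject, .data$group, .data$trial)
  out <- peaks |>
    dplyr::reframe(
      {
        fit <- fit_peak_lmm(dplyr::pick(dplyr::everything()), reml = reml)
        lmm_features(fit)
      },
      .by = "trial"
    )
  dplyr::left_join(keys, out, by = c("subject", "trial"))
}

#' @export
#' @method print peak_lmm
print.peak_lmm <- function(x, ...) {
  cat(sprintf("Peak-height mixed model (%s): %d subjects, %d peaks\n",
              if (x$reml) "REML" else "ML", x$n_subjects, x$n_peaks))
  cat(sprintf("  fixed effects: intercept %.4f, curvature slope %.4f\n",
              x$beta0, x$beta1))
  cat(sprintf("  variances: sigma2_0 %.4f, sigma2_1 %.4f, residual %.4f\n",
              x$sigma2_0, x$sigma2_1, x$sigma2))
  invisible(x)
}

#' @export
tidy.peak_lmm <- function(x, ...) {
  se <- sqrt(diag(as.matrix(stats::vcov(x$model))))
  tibble(term = c("(Intercept)", "curvature"),
         estimate = c(x$beta0, x$beta1),
         std.error = unname(se))
}

#' @export
glance.peak_lmm <- function(x, ...) {
  tibble(sigma2 = x$sigma2, sigma2_intercept = x$sigma2_0,
         sigma2_slope = x$sigma2_1, loglik = x$loglik,
         n_subjects = x$n_subjects, n_peaks = x$n_peaks, reml = x$reml)
}
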