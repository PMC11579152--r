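#' Local surrogate explanations for every subject
#'
#' LIME-style explanation of a trained continuous scorer: for each subject,
#' feature vectors are perturbed with per-feature Gaussian noise
#' (`noise_scale` times the feature's SD in the table), the scorer is
#' evaluated on the perturbations, samples are weighted by an exponential
#' kernel on standardised Euclidean distance from the subject, and a sparse
#' local linear surrogate retaining `K` features is fitted by K-Lasso: the
#' lasso path selects the `K` active features, then a kernel-weighted
#' least-squares fit on those features yields the reported weights (on the
#' raw feature scale, so a linear scorer is recovered directly).
#'
#' @param model A trained `thetanav_model` (see [train_classifier()]) or a
#'   function mapping a feature matrix to numeric scores.
#' @param table The `feature_table` whose subjects are explained.
#' @param K Number of features retained per subject.
#' @param n_samples Perturbations per subject.
#' @param noise_scale Perturbation SD as a multiple of each feature's SD.
#' @param kernel_width Width of the exponential kernel
#'   `exp(-d^2 / width^2)`; default `0.75 * sqrt(n_features)`.
#' @param seed Integer seed for the perturbations.
#' @return An object of class `explanation_record`: a tibble with one row
#'   per subject and retained feature (`subject`, `group`, `trial`,
#'   `feature`, `weight`).
#' @export
explain_subjects <- function(model, table, K = 3, n_samples = 500,
                             noise_scale = 0.25, kernel_width = NULL,
                             seed = 1L) {
  scorer <- if (is.function(model)) model else function(X) score_classifier(model, X)
  X <- feature_matrix(table)
  p <- ncol(X)
  sds <- apply(X, 2, sd)
  if (all(!is.finite(sds) | sds == 0)) {
    abort("all features are constant: perturbation variance is degenerate",
          class = "thetanav_config_error")
  }
  sds[!is.finite(sds) | sds == 0] <- 1e-12
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)
  rows <- purrr::map(seq_len(nrow(X)), function(i) {
    x0 <- X[i, ]
    Z <- with_seed(sub_seed(seed, paste0("lime-", table$subject[i])), {
      matrix(rnorm(n_samples * p, mean = rep(x0, each = n_samples),
                   sd = rep(noise_scale * sds, each = n_samples)),
             n_samples, p, dimnames = list(NULL, colnames(X)))
    })
    s <- scorer(Z)
    d2 <- rowSums(sweep(Z, 2, x0)^2 / rep(sds^2, each = n_samples))
    w <- exp(-d2 / kernel_width^2)
    if (sd(s) < 1e-12) return(NULL) # constant scorer: nothing to attribute
    sel <- klasso_select(Z, s, w, K)
    if (length(sel) == 0) return(NULL)
    fit <- stats::lm.wfit(cbind(1, Z[, sel, drop = FALSE]), s, w)
    tibble(subject = table$subject[i], group = table$group[i],
           trial = table$trial[i], feature = colnames(X)[sel],
           weight = unname(fit$coefficients[-1]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "K") <- K
  class(out) <- c("explanation_record", class(out))
  log_stage("explanations: %d subjects, K = %d", nrow(table), K)
  out
}

# lasso-path feature selection: largest set of size <= K along the path
klasso_select <- function(Z, s, w, K) {
  K <- min(K, ncol(Z))
  path <- glmnet::glmnet(Z, s, weights = w, alpha = 1, nlambda = 100)
  nz <- path$df
  ok <- which(nz <= K)
  if (length(ok) == 0) return(integer(0))
  best <- ok[which.max(nz[ok])]
  which(as.numeric(path$beta[, best]) != 0)
}

#' Top-k most frequent explanation features per group and trial
#'
#' Counts, within each (group, trial) cell, how often each feature appears
#' among the subjects' retained explanation features, and returns the `k`
#' most frequent with their mean absolute surrogate weight.
#'
#' @param record An `explanation_record` from [explain_subjects()] (several
#'   records for different trials can be row-bound first).
#' @param k Number of features to list per (group, trial).
#' @return A tibble with columns `group`, `trial`, `feature`, `n_subjects`,
#'   `mean_abs_weight`, ranked within each cell.
#' @export
top_frequent_features <- function(record, k = 3) {
  record |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     mean_abs_weight = mean(abs(.data$weight)),
                     .by = c("group", "trial", "feature")) |>
    dplyr::arrange(.data$group, .data$trial,
                   dplyr::desc(.data$n_subjects), dplyr::desc(.data$mean_abs_weight)) |>
    dplyr::slice_head(n = k, by = c("group", "trial"))
}
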