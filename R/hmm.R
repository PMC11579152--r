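#' Construct and validate Gaussian HMM parameters
#'
#' A Gaussian hidden Markov model with `M` latent states: a first-order
#' Markov chain `C_t` over states `1..M` with transition matrix `P` (rows
#' sum to 1) and initial distribution `delta`, and conditionally independent
#' Gaussian emissions `X_t | C_t = m ~ N(mean[m], var[m])`.
#'
#' @param means,variances Numeric vectors of length `M`; variances > 0.
#' @param transition `M x M` stochastic matrix.
#' @param initial Initial state distribution; defaults to uniform.
#' @return A list of class `gaussian_hmm_params`.
#' @export
gaussian_hmm_params <- function(means, variances, transition,
                                initial = rep(1 / length(means), length(means))) {
  M <- length(means)
  stopifnot(length(variances) == M, length(initial) == M)
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    abort("emission variances must be positive", class = "thetanav_validation_error")
  }
  transition <- matrix(as.numeric(transition), M, M)
  assert_prob_matrix(transition)
  assert_prob_vector(initial)
  structure(list(M = M, means = as.numeric(means),
                 variances = as.numeric(variances),
                 transition = transition, initial = as.numeric(initial)),
            class = "gaussian_hmm_params")
}

# T x M matrix of emission densities
emission_dens <- function(params, x) {
  vapply(seq_len(params$M),
         function(m) dnorm(x, params$means[m], sqrt(params$variances[m])),
         numeric(length(x)))
}

# scaled forward pass; returns list(alpha, scale, loglik)
forward_pass <- function(params, x, B = emission_dens(params, x)) {
  T_ <- length(x); M <- params$M
  B <- matrix(B, T_, M)
  alpha <- matrix(0, T_, M)
  scale <- numeric(T_)
  a <- params$initial * B[1, ]
  scale[1] <- sum(a)
  if (scale[1] <= 0) scale[1] <- .Machine$double.xmin
  alpha[1, ] <- a / scale[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- (alpha[t - 1, ] %*% params$transition) * B[t, ]
      scale[t] <- sum(a)
      if (scale[t] <= 0) scale[t] <- .Machine$double.xmin
      alpha[t, ] <- a / scale[t]
    }
  }
  list(alpha = alpha, scale = scale, loglik = sum(log(scale)))
}

#' Log-likelihood of a series under a Gaussian HMM
#'
#' Computes `log P(x_1..x_T | params)` with the scaled forward recursion,
#' which avoids underflow for long series.
#'
#' @param params A [gaussian_hmm_params()] object.
#' @param x Numeric observation vector.
#' @return The log-likelihood (a scalar).
#' @export
forward_loglik <- function(params, x) {
  stopifnot(length(x) >= 1)
  forward_pass(params, x)$loglik
}

# scaled backward pass, consistent with forward_pass scaling
backward_pass <- function(params, x, B, scale) {
  T_ <- length(x); M <- params$M
  beta <- matrix(0, T_, M)
  beta[T_, ] <- 1
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      beta[t, ] <- (params$transition %*% (B[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
    }
  }
  beta
}

#' Most probable state path (Viterbi decoding)
#'
#' Dynamic-programming maximisation of the joint path probability
#' `P(c_1..c_T, x_1..x_T)`, in log space.
#'
#' @inheritParams forward_loglik
#' @return Integer state path of length `length(x)`.
#' @export
viterbi_decode <- function(params, x) {
  T_ <- length(x); M <- params$M
  logB <- matrix(0, T_, M)
  for (m in seq_len(M)) {
    logB[, m] <- dnorm(x, params$means[m], sqrt(params$variances[m]), log = TRUE)
  }
  logP <- log(pmax(params$transition, .Machine$double.xmin))
  v <- log(pmax(params$initial, .Machine$double.xmin)) + logB[1, ]
  back <- matrix(0L, T_, M)
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- v + logP            # cand[i, j] = v_i + log P_ij
      back[t, ] <- max.col(t(cand), ties.method = "first")
      v <- cand[cbind(back[t, ], seq_len(M))] + logB[t, ]
    }
  }
  path <- integer(T_)
  path[T_] <- which.max(v)
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

#' State occupancy frequencies of a decoded path
#'
#' @param path Integer state sequence.
#' @param M Number of states.
#' @return Length-`M` vector of occupancy proportions (sums to 1).
#' @export
state_frequencies <- function(path, M) {
  stopifnot(length(path) >= 1, all(path >= 1), all(path <= M))
  tabulate(path, nbins = M) / length(path)
}

hmm_n_params <- function(M) M^2 + 2 * M - 1 # M means + M vars + M(M-1) + (M-1)

# one EM run from a given start; returns fit list (uncanonicalised).
# the recursion itself lives in compiled code (src/hmm_em.cpp)
em_run <- function(x, params, max_iter, tol, var_floor) {
  res <- hmm_em_cpp(x, params$initial, params$transition, params$means,
                    params$variances, max_iter, tol, var_floor)
  if (isTRUE(res$ll_decreased)) {
    warn("EM log-likelihood decreased during fitting")
  }
  list(params = gaussian_hmm_params(res$means, res$variances, res$transition,
                                    initial = res$initial),
       loglik = res$loglik, n_iter = res$n_iter, converged = res$converged,
       variance_floored = res$variance_floored)
}

canonicalise_hmm <- function(fit) {
  ord <- order(fit$params$means, fit$params$variances)
  p <- fit$params
  fit$params <- gaussian_hmm_params(p$means[ord], p$variances[ord],
                                    p$transition[ord, ord, drop = FALSE],
                                    p$initial[ord])
  if (!is.null(fit$decoded_path)) {
    relabel <- match(seq_along(ord), ord)
    fit$decoded_path <- relabel[fit$decoded_path]
  }
  fit
}

#' Fit a Gaussian HMM to one series by EM (Baum-Welch)
#'
#' Runs expectation-maximisation from several seeded initialisations and
#' keeps the best log-likelihood. Means are initialised at series quantiles
#' with seeded jitter, variances at the sample variance, transitions near
#' uniform with a mild diagonal boost; the initial distribution is a free
#' parameter. States are canonically reordered by ascending mean (ties by
#' ascending variance) so features are comparable across subjects — state
#' labels are otherwise arbitrary. Emission variances are floored at
#' `1e-6 * var(x)` to prevent collapse, and flagged when the floor binds.
#'
#' @param x Numeric series (length at least `10 * M` by default rule of
#'   thumb; override with `min_length`).
#' @param M Number of latent states.
#' @param seed Integer seed controlling the restarts.
#' @param n_restarts Number of seeded initialisations.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   relative log-likelihood change below `tol`.
#' @param min_length Minimum admissible series length.
#' @return An object of class `hmm_fit`: fitted `params`, `loglik`, `aic`
#'   (`-2 loglik + 2 (M^2 + 2M - 1)`), Viterbi `decoded_path`, posterior
#'   state-occupancy (`posterior_occupancy`), iteration count and
#'   convergence flags.
#' @export
fit_gaussian_hmm <- function(x, M, seed = 1L, n_restarts = 5L,
                             max_iter = 500L, tol = 1e-8,
                             min_length = 10L * M) {
  stopifnot(M >= 1)
  if (length(x) < max(min_length, 3)) {
    abort(sprintf("series too short (%d) to fit M=%d states", length(x), M),
          class = "thetanav_validation_error")
  }
  var_floor <- 1e-6 * var(x)
  sdx <- sd(x)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(sub_seed(seed, paste0("hmm-restart-", r)), {
      mu0 <- quantile(x, probs = seq_len(M) / (M + 1), names = FALSE)
      if (r > 1) mu0 <- mu0 + rnorm(M, 0, 0.25 * sdx)
      P0 <- matrix(1, M, M) + diag(M) * 2
      if (r > 1) P0 <- P0 * matrix(runif(M * M, 0.5, 1.5), M, M)
      P0 <- P0 / rowSums(P0)
      gaussian_hmm_params(mu0, rep(max(var(x), var_floor), M), P0)
    })
    run <- em_run(x, init, max_iter = max_iter, tol = tol, var_floor = var_floor)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  fit <- best
  fit$decoded_path <- viterbi_decode(fit$params, x)
  fit <- canonicalise_hmm(fit)
  # posterior occupancy under the final (canonical) parameters
  B <- emission_dens(fit$params, x)
  fw <- forward_pass(fit$params, x, B)
  bw <- backward_pass(fit$params, x, B, fw$scale)
  gamma <- fw$alpha * bw
  fit$posterior_occupancy <- colMeans(gamma / rowSums(gamma))
  fit$n_obs <- length(x)
  fit$n_params <- hmm_n_params(M)
  fit$aic <- -2 * fit$loglik + 2 * fit$n_params
  if (!fit$converged) warn(sprintf("EM did not converge in %d iterations", max_iter))
  class(fit) <- "hmm_fit"
  fit
}

#' @export
#' @method print hmm_fit
print.hmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian HMM fit: M = %d, T = %d, logLik = %.3f, AIC = %.3f\n",
              x$params$M, x$n_obs, x$loglik, x$aic))
  cat(sprintf("  converged: %s (%d EM iterations)\n", x$converged, x$n_iter))
  invisible(x)
}

#' Feature vector from a fitted HMM
#'
#' Emits the per-subject HMM features: the `M` canonically ordered state
#' means and `M` variances, plus the first `M - 1` state-occupancy
#' frequencies (the last frequency is redundant since they sum to 1). With
#' the default `M = 4` this is 8 parameter features + 3 frequency features.
#' Transition probabilities are excluded by default; `include_transitions`
#' adds the `M (M - 1)` free entries.
#'
#' @param fit An `hmm_fit` object.
#' @param include_transitions Add the off-diagonal-normalised transition
#'   probabilities `p_ij` (all entries except the last column, which is
#'   determined row-wise)?
#' @param freq_method Occupancy from the Viterbi path (default) or from
#'   posterior marginals.
#' @return A named numeric vector (`hmm_mean_*`, `hmm_var_*`, `hmm_freq_*`,
#'   optionally `hmm_p_*`).
#' @export
hmm_features <- function(fit, include_transitions = FALSE,
                         freq_method = c("viterbi", "posterior")) {
  freq_method <- match.arg(freq_method)
  M <- fit$params$M
  freq <- switch(freq_method,
                 viterbi = state_frequencies(fit$decoded_path, M),
                 posterior = fit$posterior_occupancy)
  out <- c(setNames(fit$params$means, paste0("hmm_mean_", seq_len(M))),
           setNames(fit$params$variances, paste0("hmm_var_", seq_len(M))))
  if (M > 1) out <- c(out, setNames(freq[-M], paste0("hmm_freq_", seq_len(M - 1))))
  if (include_transitions) {
    P <- fit$params$transition
    idx <- which(col(P) < M) # last column redundant per row
    out <- c(out, setNames(P[idx],
                           paste0("hmm_p_", row(P)[idx], "_", col(P)[idx])))
  }
  out
}

#' HMM features for every series of a cohort
#'
#' Fits one Gaussian HMM per `(subject, trial)` theta series and assembles
#' the feature vectors into a subjects-by-features tibble, alongside fit
#' diagnostics.
#'
#' @param theta A (standardised) `theta_df` tibble.
#' @param M Number of states (default 4).
#' @param seed Master seed; each series gets its own restart substream.
#' @param n_restarts EM restarts per series.
#' @param include_transitions,freq_method Passed to [hmm_features()].
#' @param min_length Minimum admissible series length (default `3 * M`:
#'   learner trials can be short, and a feature vector is still required for
#'   every subject even when the per-series fit is noisy).
#' @return A tibble with one row per subject and trial: feature columns plus
#'   `loglik`, `aic`, `n_iter`, `converged`.
#' @export
hmm_feature_table <- function(theta, M = 4, seed = 1L, n_restarts = 5L,
                              include_transitions = FALSE,
                              freq_method = c("viterbi", "posterior"),
                              min_length = 3L * M) {
  freq_method <- match.arg(freq_method)
  keys <- dplyr::distinct(as_tibble(theta), .data$subject, .data$group, .data$trial)
  rows <- purrr::pmap(keys, function(subject, group, trial) {
    x <- theta$theta[theta$subject == subject & theta$trial == trial]
    fit <- fit_gaussian_hmm(x, M = M,
                            seed = sub_seed(seed, paste0("hmm-", subject, "-", trial)),
                            n_restarts = n_restarts, min_length = min_length)
    feats <- hmm_features(fit, include_transitions = include_transitions,
                          freq_method = freq_method)
    tibble(subject = subject, group = group, trial = trial,
           !!!as.list(feats),
           loglik = fit$loglik, aic = fit$aic,
           n_iter = fit$n_iter, converged = fit$converged)
  })
  out <- dplyr::bind_rows(rows)
  log_stage("HMM features (M=%d): %d series x %d features", M, nrow(out),
            sum(grepl("^hmm_", names(out))))
  out
}

#' AIC profile over candidate state counts
#'
#' Fits every series at each candidate `M` and tabulates the AIC, enabling
#' the box-plot comparison used to choose the default `M = 4`. Per-series
#' failures are recorded (`NA` AIC) rather than aborting the profile.
#'
#' @param theta A (standardised) `theta_df` tibble.
#' @param M_values Candidate state counts.
#' @inheritParams hmm_feature_table
#' @return A tibble with columns `subject`, `trial`, `M`, `loglik`, `aic`,
#'   `converged`, `error`.
#' @export
aic_profile <- function(theta, M_values = 2:5, seed = 1L, n_restarts = 5L) {
  keys <- dplyr::distinct(as_tibble(theta), .data$subject, .data$trial)
  grid <- tidyr::crossing(keys, M = as.integer(M_values))
  rows <- purrr::pmap(grid, function(subject, trial, M) {
    x <- theta$theta[theta$subject == subject & theta$trial == trial]
    res <- tryCatch(
      fit_gaussian_hmm(x, M = M,
                       seed = sub_seed(seed, paste0("aic-", subject, "-", trial, "-", M)),
                       n_restarts = n_restarts),
      error = function(e) e)
    if (inherits(res, "error")) {
      tibble(subject = subject, trial = trial, M = M, loglik = NA_real_,
             aic = NA_real_, converged = NA, error = conditionMessage(res))
    } else {
      tibble(subject = subject, trial = trial, M = M, loglik = res$loglik,
             aic = res$aic, converged = res$converged, error = NA_character_)
    }
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.hmm_fit <- function(x, ...) {
  M <- x$params$M
  tibble(state = seq_len(M),
         mean = x$params$means,
         variance = x$params$variances,
         initial = x$params$initial,
         viterbi_freq = state_frequencies(x$decoded_path, M),
         posterior_freq = x$posterior_occupancy)
}

#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(M = x$params$M, n_obs = x$n_obs, loglik = x$loglik, aic = x$aic,
         n_params = x$n_params, n_iter = x$n_iter, converged = x$converged)
}
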