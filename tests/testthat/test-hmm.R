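test_that("scaled forward log-likelihood matches exhaustive path enumeration", {
  withr::with_seed(31, {
    for (i in 1:20) {
      M <- sample(1:3, 1)
      T_ <- sample(2:6, 1)
      p <- random_hmm_params(M)
      x <- rnorm(T_, sample(p$means, 1), 1)
      expect_equal(forward_loglik(p, x), enumerate_loglik(p, x), tolerance = 1e-8)
    }
  })
})

test_that("forward log-likelihood closed forms: single state and length one", {
  withr::with_seed(32, {
    p1 <- gaussian_hmm_params(0.5, 2, matrix(1, 1, 1))
    x <- rnorm(40)
    expect_equal(forward_loglik(p1, x),
                 sum(dnorm(x, 0.5, sqrt(2), log = TRUE)), tolerance = 1e-10)
    p3 <- random_hmm_params(3)
    x1 <- rnorm(1)
    expect_equal(forward_loglik(p3, x1),
                 log(sum(p3$initial * dnorm(x1, p3$means, sqrt(p3$variances)))),
                 tolerance = 1e-10)
  })
})

test_that("Viterbi decodes the jointly most probable path", {
  p1 <- gaussian_hmm_params(0, 1, matrix(1, 1, 1))
  expect_equal(viterbi_decode(p1, rnorm(10)), rep(1L, 10))
  withr::with_seed(33, {
    for (i in 1:8) {
      M <- sample(2:3, 1)
      p <- random_hmm_params(M)
      x <- rnorm(6, sample(p$means, 1), 1)
      paths <- as.matrix(expand.grid(rep(list(seq_len(M)), 6)))
      lj <- apply(paths, 1, function(st) path_log_joint(p, x, st))
      expect_equal(viterbi_decode(p, x), unname(paths[which.max(lj), ]))
      # Viterbi path beats the posterior-marginal argmax path
      vit <- viterbi_decode(p, x)
      post <- exp(vapply(seq_len(M), function(m) {
        vapply(seq_len(6), function(t) {
          xs <- paths[, t] == m
          matrixStats_logsum <- max(lj[xs]) + log(sum(exp(lj[xs] - max(lj[xs]))))
          matrixStats_logsum
        }, numeric(1))
      }, numeric(6)))
      marg <- apply(post, 1, which.max)
      expect_gte(path_log_joint(p, x, vit), path_log_joint(p, x, marg) - 1e-12)
    }
  })
})

test_that("state frequencies are exact occupancy counts", {
  expect_equal(state_frequencies(c(1, 1, 2, 2), 2), c(0.5, 0.5))
  expect_equal(state_frequencies(rep(1, 7), 3), c(1, 0, 0))
  withr::with_seed(34, {
    path <- sample(1:4, 1000, replace = TRUE)
    expect_equal(state_frequencies(path, 4),
                 as.numeric(table(factor(path, 1:4))) / 1000)
  })
})

test_that("single-state EM reduces to sample moments and the AIC formula holds", {
  withr::with_seed(35, x <- rnorm(200, 3, 2))
  fit <- fit_gaussian_hmm(x, M = 1, seed = 1)
  expect_equal(fit$params$means, mean(x), tolerance = 1e-6)
  expect_equal(fit$params$variances, var(x) * (199 / 200), tolerance = 1e-5)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2) # n_params = 1 + 2 - 1 = 2
})

test_that("EM recovers a well-separated two-state chain", {
  truth <- gaussian_hmm_params(c(-2, 2), c(1, 1),
                               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  for (r in 1:3) {
    sim <- simulate_hmm_series(truth, 2000, seed = 400 + r)
    fit <- fit_gaussian_hmm(sim$values, M = 2, seed = r)
    expect_lt(max(abs(fit$params$means - c(-2, 2))), 0.1)
    expect_lt(max(abs(diag(fit$params$transition) - 0.9)), 0.05)
    # MLE dominance over the generating parameters
    expect_gte(fit$loglik, forward_loglik(truth, sim$values) - 1e-6)
    # decoded path recovers most hidden states
    expect_gt(mean(fit$decoded_path == sim$states), 0.9)
  }
})

test_that("larger models dominate smaller ones in fitted likelihood", {
  truth <- gaussian_hmm_params(c(-2, 2), c(1, 1),
                               matrix(c(0.85, 0.15, 0.15, 0.85), 2, 2))
  aics <- purrr::map_dfr(1:6, function(r) {
    x <- simulate_hmm_series(truth, 300, seed = 500 + r)$values
    f1 <- fit_gaussian_hmm(x, M = 1, seed = r)
    f2 <- fit_gaussian_hmm(x, M = 2, seed = r)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
    tibble::tibble(aic1 = f1$aic, aic2 = f2$aic)
  })
  # strong separation: two states clearly preferred
  expect_lt(median(aics$aic2), median(aics$aic1))
})

test_that("feature vectors have the documented size and canonical order", {
  truth <- gaussian_hmm_params(c(-3, -1, 1, 3), rep(0.5, 4),
                               {P <- matrix(0.05, 4, 4); diag(P) <- 0.85; P})
  x <- simulate_hmm_series(truth, 600, seed = 9)$values
  fit4 <- fit_gaussian_hmm(x, M = 4, seed = 2)
  f4 <- hmm_features(fit4)
  expect_length(f4, 11) # 4 means + 4 variances + 3 frequencies
  expect_named(f4, c(paste0("hmm_mean_", 1:4), paste0("hmm_var_", 1:4),
                     paste0("hmm_freq_", 1:3)))
  expect_false(is.unsorted(fit4$params$means))
  fit2 <- fit_gaussian_hmm(x, M = 2, seed = 2)
  expect_length(hmm_features(fit2), 5)
  ft <- hmm_features(fit4, include_transitions = TRUE)
  expect_length(ft, 11 + 4 * 3)
  # restarts from different seeds agree after canonical relabelling
  fit4b <- fit_gaussian_hmm(x, M = 4, seed = 77)
  expect_equal(hmm_features(fit4b)[1:8], f4[1:8], tolerance = 1e-3)
  # posterior occupancy is a distribution
  expect_equal(sum(fit4$posterior_occupancy), 1, tolerance = 1e-8)
  expect_equal(sum(hmm_features(fit4, freq_method = "posterior")[9:11] >= 0), 3)
})

test_that("aic_profile tabulates fits per series and records failures", {
  co <- tiny_cohort()
  th <- standardise_theta(co$theta, "zscore")
  sub <- dplyr::filter(th, subject %in% c("L01", "N01"))
  prof <- aic_profile(sub, M_values = 1:2, seed = 5)
  expect_equal(nrow(prof), 4 * 2)
  ok <- !is.na(prof$aic)
  expect_true(any(ok))
  expect_equal(prof$aic[ok], -2 * prof$loglik[ok] +
                 2 * (prof$M[ok]^2 + 2 * prof$M[ok] - 1))
})

test_that("simulated series obey degenerate chains and stationary occupancy", {
  p1 <- gaussian_hmm_params(0, 1, matrix(1, 1, 1))
  s1 <- simulate_hmm_series(p1, 5000, seed = 6)
  expect_equal(mean(s1$values), 0, tolerance = 0.05)
  expect_equal(sd(s1$values), 1, tolerance = 0.05)
  # absorbing chain started in state 1 stays there
  p_abs <- gaussian_hmm_params(c(0, 5), c(1, 1), diag(2), initial = c(1, 0))
  s_abs <- simulate_hmm_series(p_abs, 100, seed = 7)
  expect_equal(s_abs$states, rep(1L, 100))
  # occupancy matches the stationary distribution of P
  P <- matrix(c(0.8, 0.2, 0.4, 0.6), 2, 2, byrow = TRUE)
  p2 <- gaussian_hmm_params(c(-2, 2), c(1, 1), P)
  s2 <- simulate_hmm_series(p2, 5000, seed = 8)
  statn <- Re(eigen(t(P))$vectors[, 1]); statn <- statn / sum(statn)
  expect_lt(max(abs(state_frequencies(s2$states, 2) - statn)), 0.03)
})

test_that("invalid HMM inputs are rejected", {
  expect_error(gaussian_hmm_params(c(0, 1), c(1, -1), diag(2)),
               class = "thetanav_validation_error")
  expect_error(gaussian_hmm_params(c(0, 1), c(1, 1),
                                   matrix(c(0.5, 0.2, 0.5, 0.2), 2, 2)),
               class = "thetanav_validation_error")
  expect_error(fit_gaussian_hmm(rnorm(5), M = 2, seed = 1),
               class = "thetanav_validation_error")
})
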