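test_that("peak detection finds strict interior maxima with their curvature", {
  pk <- detect_peaks(c(0, 1, 0))
  expect_equal(pk$index, 2)
  expect_equal(pk$height, 1)
  expect_equal(pk$curvature, -2)
  expect_equal(nrow(detect_peaks(1:10)), 0)
  expect_equal(nrow(detect_peaks(10:1)), 0)
  # plateau peak counts once, at its first index
  pk2 <- detect_peaks(c(0, 2, 2, 0, 3, 0))
  expect_equal(pk2$index, c(2, 5))
  # sine over 3 periods has 3 peaks; brute-force scan agrees
  x <- sin(2 * pi * seq(0, 3, length.out = 301))[-301]
  pk3 <- detect_peaks(x)
  expect_equal(nrow(pk3), 3)
  brute <- which(vapply(2:(length(x) - 1), function(k) {
    x[k - 1] < x[k] && x[k] > x[k + 1]
  }, logical(1))) + 1
  expect_equal(pk3$index, brute)
})

test_that("curvature is the second-order difference", {
  expect_equal(peak_curvature(c(2, 5, 3), 2), -5)
  expect_equal(peak_curvature(rep(4, 3), 2), 0)
  a <- 0.37
  xq <- a * (0:4)^2
  expect_equal(peak_curvature(xq, 3), 2 * a, tolerance = 1e-12)
  expect_error(peak_curvature(c(1, 2, 3), 1), class = "thetanav_index_error")
  expect_error(peak_curvature(c(1, 2, 3), 3), class = "thetanav_index_error")
})

test_that("fitted marginal likelihood matches closed-form and quadrature oracles", {
  peaks <- simulate_lmm_data(3, 6, beta0 = 1.5, beta1 = -0.4,
                             sigma2_0 = 0.8, sigma2_1 = 0.2, sigma2 = 0.3,
                             seed = 51)
  fit <- fit_peak_lmm(peaks, reml = FALSE)
  direct <- lmm_marginal_loglik(fit$beta0, fit$beta1, fit$sigma2,
                                fit$sigma2_0, fit$sigma2_1, peaks)
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
  quad <- lmm_quadrature_loglik(fit$beta0, fit$beta1, fit$sigma2,
                                fit$sigma2_0, fit$sigma2_1, peaks)
  expect_equal(quad, direct, tolerance = 1e-6)
})

test_that("closed-form BLUPs agree with the mixed-model software's predictions", {
  peaks <- simulate_lmm_data(12, 8, beta0 = 2, beta1 = -0.5,
                             sigma2_0 = 1, sigma2_1 = 0.25, sigma2 = 0.5,
                             seed = 52)
  fit <- fit_peak_lmm(peaks)
  re <- lme4::ranef(fit$model)$subject
  expect_equal(fit$per_subject$lmm_intercept,
               fit$beta0 + re[fit$per_subject$subject, "(Intercept)"],
               tolerance = 1e-5)
  re_all <- lme4::ranef(fit$model)
  re_s <- re_all[[which(vapply(re_all, function(d) "curvature" %in% names(d),
                               logical(1)))[1]]]
  expect_equal(fit$per_subject$lmm_slope,
               fit$beta1 + re_s[fit$per_subject$subject, "curvature"],
               tolerance = 1e-5)
})

test_that("BLUPs shrink each subject toward the fixed effects", {
  peaks <- simulate_lmm_data(15, 10, beta0 = 2, beta1 = -0.5,
                             sigma2_0 = 1, sigma2_1 = 0.25, sigma2 = 0.8,
                             seed = 53)
  fit <- fit_peak_lmm(peaks)
  # shrinkage holds in the per-subject information metric: the BLUP
  # deviation from the fixed effects is never larger (in the Z'Z norm)
  # than the subject's own least-squares deviation
  beta <- c(fit$beta0, fit$beta1)
  for (s in unique(peaks$subject)) {
    d <- dplyr::filter(peaks, subject == s)
    Z <- cbind(1, d$curvature)
    S <- crossprod(Z)
    b_ols <- coef(stats::lm(height ~ curvature, data = d))
    blup <- fit$per_subject[fit$per_subject$subject == s, ]
    u_blup <- c(blup$lmm_intercept, blup$lmm_slope) - beta
    u_ols <- unname(b_ols) - beta
    expect_lte(drop(t(u_blup) %*% S %*% u_blup),
               drop(t(u_ols) %*% S %*% u_ols) + 1e-8)
  }
})

test_that("degenerate and symmetric cases collapse as expected", {
  # no between-subject variability: BLUPs match the fixed effects
  peaks0 <- simulate_lmm_data(10, 12, beta0 = 1, beta1 = -0.3,
                              sigma2_0 = 0, sigma2_1 = 0, sigma2 = 0.2,
                              seed = 54)
  fit0 <- fit_peak_lmm(peaks0)
  expect_lt(fit0$sigma2_0, 0.05)
  expect_lt(fit0$sigma2_1, 0.05)
  expect_lt(max(abs(fit0$per_subject$lmm_intercept - fit0$beta0)), 0.1)
  expect_lt(max(abs(fit0$per_subject$lmm_slope - fit0$beta1)), 0.1)
  expect_true(all(c(fit0$sigma2, fit0$sigma2_0, fit0$sigma2_1) >= 0))
  # duplicated subjects receive identical BLUPs
  one <- simulate_lmm_data(1, 10, 2, -0.5, 1, 0.25, 0.5, seed = 55)
  two <- dplyr::bind_rows(dplyr::mutate(one, subject = "A"),
                          dplyr::mutate(one, subject = "B"))
  fit2 <- fit_peak_lmm(two)
  ps <- fit2$per_subject
  expect_equal(ps$lmm_intercept[ps$subject == "A"],
               ps$lmm_intercept[ps$subject == "B"], tolerance = 1e-8)
  expect_equal(ps$lmm_slope[ps$subject == "A"],
               ps$lmm_slope[ps$subject == "B"], tolerance = 1e-8)
})

test_that("too little data is rejected; features carry the documented names", {
  expect_error(fit_peak_lmm(tibble::tibble(subject = c("a", "b"),
                                           height = c(1, 2),
                                           curvature = c(-1, -2))),
               class = "thetanav_fit_error")
  peaks <- simulate_lmm_data(8, 6, 2, -0.5, 1, 0.25, 0.5, seed = 56)
  fit <- fit_peak_lmm(peaks)
  feats <- lmm_features(fit)
  expect_named(feats, c("subject", "lmm_intercept", "lmm_slope"))
  expect_equal(nrow(feats), 8)
})

test_that("held-out BLUP prediction works for unseen subjects", {
  peaks <- simulate_lmm_data(20, 10, 2, -0.5, 1, 0.25, 0.5, seed = 57)
  train <- dplyr::filter(peaks, subject != "S01")
  held <- dplyr::filter(peaks, subject == "S01")
  fit <- fit_peak_lmm(train)
  pred <- predict_blups(fit, held)
  expect_equal(nrow(pred), 1)
  # prediction shrinks the subject's own fit toward the population line
  # in the subject's information metric
  Z <- cbind(1, held$curvature)
  S <- crossprod(Z)
  beta <- c(fit$beta0, fit$beta1)
  u_blup <- c(pred$lmm_intercept, pred$lmm_slope) - beta
  u_ols <- unname(coef(stats::lm(height ~ curvature, data = held))) - beta
  expect_lte(drop(t(u_blup) %*% S %*% u_blup),
             drop(t(u_ols) %*% S %*% u_ols) + 1e-8)
})

test_that("per-trial LMM features cover every cohort subject", {
  co <- tiny_cohort()
  th <- standardise_theta(co$theta, "zscore")
  lf <- lmm_feature_table(th)
  expect_equal(nrow(lf), 16)
  expect_false(anyNA(lf$lmm_slope))
})
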