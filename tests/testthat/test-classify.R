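# small helper: wrap a feature matrix into a feature_table
make_table <- function(X, label) {
  stopifnot(nrow(X) == length(label))
  tab <- tibble::tibble(subject = sprintf("s%02d", seq_along(label)),
                        group = ifelse(label == 1, "learner", "non_learner"),
                        trial = 1L, label = as.integer(label)) |>
    dplyr::bind_cols(tibble::as_tibble(X))
  class(tab) <- c("feature_table", class(tab))
  tab
}

test_that("rank-based AUROC equals brute-force pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  brute_auroc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(71, {
    for (i in 1:100) {
      n <- sample(5:20, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- round(rnorm(n), sample(0:2, 1)) # rounding forces ties
      expect_identical(auroc(s, y), brute_auroc(s, y))
    }
  })
  expect_error(auroc(1:3, c(1, 1, 1)), class = "thetanav_metric_error")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(72, {
    s <- rnorm(30); y <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
    a <- auroc(s, y)
    expect_equal(auroc(exp(s), y), a)
    expect_equal(auroc(2 * s + 7, y), a)
    expect_equal(auroc(rank(s), y), a)
  })
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(73, {
    for (i in 1:10) {
      s <- rnorm(40); y <- c(0, 1, sample(0:1, 38, replace = TRUE))
      expect_equal(auroc(s, y),
                   as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
})

test_that("every classifier family trains, scores, and separates easy data", {
  withr::with_seed(74, {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 3), n, 3)
    X[, 1] <- X[, 1] + 4 * y # wide margin on one feature
    colnames(X) <- paste0("f", 1:3)
    for (nm in names(default_classifiers())) {
      model <- train_classifier(classifier_spec(nm), X, y, seed = 3)
      sc <- score_classifier(model, X)
      expect_length(sc, n)
      expect_true(all(is.finite(sc)))
      expect_gte(auroc(sc, y), 0.95)
    }
  })
  expect_error(classifier_spec("boosted_stump"), class = "thetanav_config_error")
})

test_that("LOOCV yields one held-out score per subject and detects separable data", {
  withr::with_seed(75, {
    y <- rep(c(0, 1), each = 10)
    X <- matrix(rnorm(20 * 2), 20, 2)
    X[, 1] <- X[, 1] + 6 * y
    colnames(X) <- c("f1", "f2")
    tab <- make_table(X, y)
    ev <- loocv_evaluate(tab, classifier_spec("knn"), seed = 1)
    expect_equal(nrow(ev$scores), 20)
    expect_false(anyNA(ev$scores$score))
    expect_equal(ev$auroc, 1.0)
  })
})

test_that("permuted labels give chance-level LOOCV AUROC on average", {
  withr::with_seed(76, {
    X <- matrix(rnorm(30 * 4), 30, 4)
    colnames(X) <- paste0("f", 1:4)
    y0 <- rep(c(0, 1), each = 15)
    aucs <- vapply(1:50, function(i) {
      tab <- make_table(X, sample(y0))
      loocv_evaluate(tab, classifier_spec("knn"), seed = i)$auroc
    }, numeric(1))
    expect_gte(mean(aucs), 0.4)
    expect_lte(mean(aucs), 0.6)
  })
})

test_that("LOOCV validates its inputs", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(loocv_evaluate(make_table(X, rep(1, 4)), classifier_spec("knn")),
               class = "thetanav_validation_error")
  expect_error(loocv_evaluate(make_table(X[1:3, ], c(1, 0, 1)),
                              classifier_spec("knn")),
               class = "thetanav_validation_error")
})

test_that("fit-once and per-fold LMM modes differ only through LMM features", {
  co <- tiny_cohort()
  th <- standardise_theta(co$theta, "zscore")
  hf <- hmm_feature_table(th, M = 2, seed = 5)
  lf <- lmm_feature_table(th)
  tf <- trajectory_features(co$coords)
  du <- series_durations(th)
  pk <- dplyr::filter(peak_table(th), trial == 12)
  tab <- assemble_feature_table(hf, lf, tf, variant = "eeg", trial = 12,
                                durations = du)
  spec <- classifier_spec("knn")
  # with LMM columns removed, toggling the mode cannot change anything
  tab_nolmm <- dplyr::select(tab, -lmm_intercept, -lmm_slope)
  class(tab_nolmm) <- c("feature_table", class(tab_nolmm))
  a <- loocv_evaluate(tab_nolmm, spec, seed = 2, peaks = pk,
                      lmm_mode = "per_fold")
  b <- loocv_evaluate(tab_nolmm, spec, seed = 2, peaks = pk,
                      lmm_mode = "fit_once")
  expect_identical(a$scores$score, b$scores$score)
  # with LMM columns present the held-out features (and only they) change
  c1 <- loocv_evaluate(tab, spec, seed = 2, peaks = pk, lmm_mode = "per_fold")
  c2 <- loocv_evaluate(tab, spec, seed = 2, peaks = pk, lmm_mode = "fit_once")
  expect_equal(c1$lmm_mode, "per_fold")
  expect_equal(c2$lmm_mode, "fit_once")
})

test_that("feature tables assemble with the documented column counts", {
  co <- tiny_cohort()
  th <- standardise_theta(co$theta, "zscore")
  hf <- hmm_feature_table(th, M = 4, seed = 5)
  lf <- lmm_feature_table(th)
  tf <- trajectory_features(co$coords)
  du <- series_durations(th)
  tab_c <- assemble_feature_table(traj_feats = tf, variant = "coordinates",
                                  trial = 12)
  expect_equal(ncol(tab_c) - 4, 4) # exactly the four behavioural features
  tab_e <- assemble_feature_table(hf, lf, variant = "eeg", trial = 12,
                                  durations = du)
  expect_equal(ncol(tab_e) - 4, 11 + 2 + 1) # HMM + LMM + duration
  tab_b <- assemble_feature_table(hf, lf, tf, variant = "combined", trial = 12,
                                  durations = du)
  expect_setequal(setdiff(names(tab_b), names(tab_e)),
                  setdiff(names(tab_c), c("subject", "group", "trial", "label")))
  expect_equal(tab_b$label, as.integer(tab_b$group == "learner"))
  # missing subject in one source is an assembly error naming the subject
  expect_error(assemble_feature_table(dplyr::filter(hf, subject != "L01"),
                                      lf, variant = "eeg", trial = 12,
                                      durations = du),
               class = "thetanav_assembly_error", regexp = "L01")
})

test_that("the MLP is deterministic given a seed and learns a margin", {
  withr::with_seed(77, {
    y <- rep(c(0, 1), each = 15)
    X <- matrix(rnorm(30 * 2), 30, 2)
    X[, 2] <- X[, 2] + 3 * y
    m1 <- mlp_fit(X, y, hidden = c(8, 4), epochs = 300, seed = 9)
    m2 <- mlp_fit(X, y, hidden = c(8, 4), epochs = 300, seed = 9)
    expect_identical(predict(m1, X), predict(m2, X))
    expect_gte(auroc(predict(m1, X), y), 0.95)
  })
})
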