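options(thetanav.quiet = TRUE)

# small, fast cohort reused across tests
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(cohort_spec(n_per_group = 4, duration = 30, seed = 7))
    }
    cache
  }
})

# brute-force HMM log-likelihood by exhaustive path enumeration
enumerate_loglik <- function(params, x) {
  M <- params$M
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    pr <- params$initial[st[1]] *
      prod(dnorm(x, params$means[st], sqrt(params$variances[st])))
    if (T_ > 1) {
      for (t in 2:T_) pr <- pr * params$transition[st[t - 1], st[t]]
    }
    total <- total + pr
  }
  log(total)
}

# joint probability of one state path (for Viterbi oracles)
path_log_joint <- function(params, x, st) {
  lp <- log(params$initial[st[1]]) +
    sum(dnorm(x, params$means[st], sqrt(params$variances[st]), log = TRUE))
  if (length(x) > 1) {
    for (t in 2:length(x)) lp <- lp + log(params$transition[st[t - 1], st[t]])
  }
  lp
}

# random stochastic matrix
random_transition <- function(M) {
  P <- matrix(runif(M * M, 0.05, 1), M, M)
  P / rowSums(P)
}

# random HMM parameter set
random_hmm_params <- function(M) {
  gaussian_hmm_params(means = sort(runif(M, -3, 3)),
                      variances = runif(M, 0.3, 2),
                      transition = random_transition(M),
                      initial = { p <- runif(M, 0.1, 1); p / sum(p) })
}

# direct multivariate-normal marginal log-likelihood of the peak LMM
# (closed-form oracle independent of lme4)
lmm_marginal_loglik <- function(beta0, beta1, sigma2, sigma2_0, sigma2_1, peaks) {
  D <- diag(c(sigma2_0, sigma2_1))
  sum(vapply(split(peaks, peaks$subject), function(d) {
    Z <- cbind(1, d$curvature)
    V <- Z %*% D %*% t(Z) + sigma2 * diag(nrow(d))
    r <- d$height - Z %*% c(beta0, beta1)
    -0.5 * (nrow(d) * log(2 * pi) + determinant(V)$modulus +
              t(r) %*% solve(V, r))
  }, numeric(1)))
}

# the same marginal likelihood by per-subject 2-D Gauss-Hermite quadrature,
# adaptively centred/scaled at each subject's conditional posterior
lmm_quadrature_loglik <- function(beta0, beta1, sigma2, sigma2_0, sigma2_1,
                                  peaks, n_nodes = 40) {
  gh <- local({ # Golub-Welsch nodes/weights for weight exp(-x^2)
    i <- seq_len(n_nodes - 1)
    a <- sqrt(i / 2)
    J <- matrix(0, n_nodes, n_nodes)
    J[cbind(i, i + 1)] <- a; J[cbind(i + 1, i)] <- a
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
  })
  vcomp <- c(sigma2_0, sigma2_1)
  active <- vcomp > 1e-10 # a zero variance component is a point mass at 0
  sum(vapply(split(peaks, peaks$subject), function(d) {
    Z <- cbind(1, d$curvature)
    # integrand: likelihood x random-effect prior over the active effects
    lik <- function(b) {
      prior <- prod(dnorm(b[active], 0, sqrt(vcomp[active])))
      prod(dnorm(d$height, (beta0 + b[1]) + (beta1 + b[2]) * d$curvature,
                 sqrt(sigma2))) * prior
    }
    if (!any(active)) return(log(lik(c(0, 0))))
    Za <- Z[, active, drop = FALSE]
    post_prec <- crossprod(Za) / sigma2 + diag(1 / vcomp[active], sum(active))
    r <- d$height - Z %*% c(beta0, beta1)
    post_mean <- solve(post_prec, crossprod(Za, r) / sigma2)
    sdv <- sqrt(diag(solve(post_prec)))
    idx <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), sum(active))))
    total <- 0
    for (row in seq_len(nrow(idx))) {
      nodes <- gh$nodes[idx[row, ]]
      b <- c(0, 0)
      b[active] <- post_mean + sqrt(2) * sdv * nodes
      total <- total + prod(gh$weights[idx[row, ]]) * lik(b) * exp(sum(nodes^2))
    }
    log(total * prod(sqrt(2) * sdv))
  }, numeric(1)))
}

# simulate peaks data from the mixed model's generative process
simulate_lmm_data <- function(n_subjects, n_peaks, beta0, beta1,
                              sigma2_0, sigma2_1, sigma2, seed) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      b0 <- rnorm(1, beta0, sqrt(sigma2_0))
      b1 <- rnorm(1, beta1, sqrt(sigma2_1))
      x <- rnorm(n_peaks, -2, 1) # curvature-like negative covariate
      tibble::tibble(subject = sprintf("S%02d", i),
                     curvature = x,
                     height = b0 + b1 * x + rnorm(n_peaks, 0, sqrt(sigma2)),
                     true_b0 = b0, true_b1 = b1)
    })
  })
}
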