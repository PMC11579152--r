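#' Specification of a synthetic cohort
#'
#' Bundles every generating parameter of the synthetic study: two groups
#' (learner / non-learner, default 25 subjects each), two trials (1 and 12),
#' a 60 s trial cap with trajectories sampled every 0.25 s on a circular
#' arena, and per-(group, trial) Gaussian-HMM truths for the theta series
#' plus kinematic truths for the trajectories.
#'
#' The default truths encode the study's qualitative structure: in trial 1
#' the generating parameters are identical across groups (nobody has learned
#' the goal location), while in trial 12 the learner group differs — its
#' theta-state means are shifted by `effect_size` state standard deviations
#' and its trajectories are biased toward the hidden goal. Non-learner trial
#' durations are time-matched to the learner duration distribution of the
#' same trial.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param duration Trial cap in seconds.
#' @param theta_rate Theta sampling rate in Hz (default 4; the method is
#'   rate-agnostic and rates up to 512 Hz are supported).
#' @param traj_dt Trajectory sampling interval in seconds.
#' @param arena_radius Arena radius in Virtual Metres.
#' @param goal Goal centre coordinates.
#' @param goal_frac Goal area as a fraction of the arena area; the goal
#'   radius is `arena_radius * sqrt(goal_frac)`.
#' @param speed Walking speed in Vm/s (constant across conditions).
#' @param effect_size Trial-12 group separation of the theta-state means, in
#'   state standard deviations.
#' @param seed Master integer seed for the whole cohort.
#' @param hmm_truth,traj_truth Optional overrides: nested lists
#'   `truth[[group]][[trial]]` of [gaussian_hmm_params()] objects /
#'   kinematic parameter lists (`goal_bias`, `heading_noise_sd`,
#'   `idle_prob`).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 25, duration = 60, theta_rate = 4,
                        traj_dt = 0.25, arena_radius = 37.5,
                        goal = c(0, 0), goal_frac = 0.15, speed = 4.76,
                        effect_size = 3, seed = 1L,
                        hmm_truth = NULL, traj_truth = NULL) {
  stopifnot(n_per_group >= 2, theta_rate > 0, duration > 0, arena_radius > 0)
  if (sqrt(sum(goal^2)) >= arena_radius) {
    abort("goal must lie inside the arena", class = "thetanav_validation_error")
  }
  base_means <- c(2, 4, 6, 8)
  base_sd <- 0.7
  sticky <- matrix(0.05, 4, 4); diag(sticky) <- 0.85
  base_hmm <- gaussian_hmm_params(base_means, rep(base_sd^2, 4), sticky)
  shifted_hmm <- gaussian_hmm_params(base_means + effect_size * base_sd,
                                     rep(base_sd^2, 4), sticky)
  if (is.null(hmm_truth)) {
    hmm_truth <- list(
      learner = list(`1` = base_hmm, `12` = shifted_hmm),
      non_learner = list(`1` = base_hmm, `12` = base_hmm)
    )
  }
  walk <- list(goal_bias = 0, heading_noise_sd = 0.6, idle_prob = 0.1)
  seek <- list(goal_bias = 0.5, heading_noise_sd = 0.6, idle_prob = 0.1)
  if (is.null(traj_truth)) {
    traj_truth <- list(
      learner = list(`1` = walk, `12` = seek),
      non_learner = list(`1` = walk, `12` = walk)
    )
  }
  structure(list(n_per_group = n_per_group, duration = duration,
                 theta_rate = theta_rate, traj_dt = traj_dt,
                 arena_radius = arena_radius, goal = goal,
                 goal_radius = arena_radius * sqrt(goal_frac),
                 speed = speed, effect_size = effect_size,
                 seed = as.integer(seed),
                 hmm_truth = hmm_truth, traj_truth = traj_truth),
            class = "cohort_spec")
}

#' Simulate one sequence from a Gaussian HMM
#'
#' Draws a hidden first-order Markov state path from the chain
#' `(initial, transition)` and emits `x_t ~ N(mean[C_t], var[C_t])`. The
#' hidden path is returned alongside the values so state-recovery tests can
#' compare decoded and true paths.
#'
#' @param params A [gaussian_hmm_params()] object.
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return A list with numeric `values` and integer `states`.
#' @export
simulate_hmm_series <- function(params, length, seed = 1L) {
  stopifnot(inherits(params, "gaussian_hmm_params"), length >= 1)
  assert_prob_matrix(params$transition)
  with_seed(seed, {
    states <- integer(length)
    states[1] <- sample.int(params$M, 1, prob = params$initial)
    if (length > 1) {
      for (t in 2:length) {
        states[t] <- sample.int(params$M, 1, prob = params$transition[states[t - 1], ])
      }
    }
    values <- rnorm(length, params$means[states], sqrt(params$variances[states]))
    list(values = values, states = states)
  })
}

#' Simulate one navigation trajectory
#'
#' A biased random walk on the circular arena: per 0.25 s step the walker
#' either idles (probability `idle_prob`) or advances `speed * dt` along a
#' heading blending its current heading with the direction to the goal
#' (weight `goal_bias`; 0 = pure random walk, 1 = straight to goal) plus
#' Gaussian heading noise. Positions are clamped to the arena. Walkers with
#' a positive goal bias, and learners generally, terminate on entering the
#' goal region; otherwise the walk runs for `duration` seconds. The start
#' position is fixed across subjects and conditions.
#'
#' @param group `"learner"` or `"non_learner"`.
#' @param trial Trial label (1 or 12).
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param duration Override for the walk duration in seconds (used for
#'   time-matching non-learners); defaults to the spec's cap.
#' @return A tibble with columns `group`, `trial`, `time`, `x`, `y`,
#'   `total_time`.
#' @export
simulate_trajectory <- function(group, trial, spec, seed = 1L,
                                duration = spec$duration) {
  kin <- spec$traj_truth[[group]][[as.character(trial)]]
  R <- spec$arena_radius
  step <- spec$speed * spec$traj_dt
  n_max <- ceiling(duration / spec$traj_dt)
  goal <- spec$goal
  seeks_goal <- group == "learner" # only learner trials end at the goal
  with_seed(seed, {
    xs <- numeric(n_max + 1); ys <- numeric(n_max + 1)
    xs[1] <- 0; ys[1] <- -0.9 * R
    heading <- pi / 2
    k <- 1
    for (t in seq_len(n_max)) {
      if (runif(1) < kin$idle_prob) {
        xs[t + 1] <- xs[t]; ys[t + 1] <- ys[t]
      } else {
        if (kin$goal_bias > 0) {
          gd <- atan2(goal[2] - ys[t], goal[1] - xs[t])
          v <- (1 - kin$goal_bias) * c(cos(heading), sin(heading)) +
            kin$goal_bias * c(cos(gd), sin(gd))
          heading <- if (sum(v^2) < 1e-12) gd else atan2(v[2], v[1])
        }
        if (kin$heading_noise_sd > 0) heading <- heading + rnorm(1, 0, kin$heading_noise_sd)
        nx <- xs[t] + step * cos(heading)
        ny <- ys[t] + step * sin(heading)
        r <- sqrt(nx^2 + ny^2)
        if (r > R) { # clamp to the wall and turn inward
          nx <- nx * R / r; ny <- ny * R / r
          heading <- atan2(-ny, -nx)
        }
        xs[t + 1] <- nx; ys[t + 1] <- ny
      }
      k <- t + 1
      if (seeks_goal &&
          sqrt((xs[k] - goal[1])^2 + (ys[k] - goal[2])^2) <= spec$goal_radius) break
    }
    tibble(group = group, trial = as.integer(trial),
           time = (seq_len(k) - 1) * spec$traj_dt,
           x = xs[seq_len(k)], y = ys[seq_len(k)],
           total_time = (k - 1) * spec$traj_dt)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates `2 * n_per_group` subjects x 2 trials of both data kinds:
#' trajectories first (learners may terminate at the goal; non-learner
#' durations are drawn from the learner duration distribution of the same
#' trial, emulating time-matching), then theta series whose length is the
#' trial duration times the theta sampling rate. Every generating parameter
#' and hidden state path is kept in the returned `truth` record so that
#' downstream recovery tests have ground truth. Bit-reproducible for a
#' given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `theta` (a `theta_df`), `coords` (a
#'   `trajectory_df`) and `truth` (generating parameters, per-series hidden
#'   state paths, durations).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("learner", "non_learner")
  ids <- list(learner = sprintf("L%02d", seq_len(spec$n_per_group)),
              non_learner = sprintf("N%02d", seq_len(spec$n_per_group)))
  coords <- list(); theta <- list()
  hidden <- list(); durations <- list()
  for (trial in c(1L, 12L)) {
    # learners first: their realised durations define the time-matching pool
    learner_traj <- purrr::map(ids$learner, function(id) {
      tr <- simulate_trajectory("learner", trial, spec,
                                seed = sub_seed(spec$seed, paste0("traj-", id, "-", trial)))
      dplyr::mutate(tr, subject = id, .before = 1)
    })
    # time-matching: each non-learner's duration is the stopping time of an
    # independent phantom walk with the learner kinematics of this trial, so
    # matched durations follow exactly the learner duration law without
    # being copies of individual learner trial times
    matched <- purrr::map_dbl(ids$non_learner, function(id) {
      simulate_trajectory("learner", trial, spec,
                          seed = sub_seed(spec$seed, paste0("match-", id, "-", trial))
      )$total_time[1]
    })
    nl_traj <- purrr::imap(ids$non_learner, function(id, i) {
      tr <- simulate_trajectory("non_learner", trial, spec,
                                seed = sub_seed(spec$seed, paste0("traj-", id, "-", trial)),
                                duration = matched[i])
      dplyr::mutate(tr, subject = id, .before = 1)
    })
    all_traj <- c(learner_traj, nl_traj)
    coords[[as.character(trial)]] <- dplyr::bind_rows(all_traj)
    for (tr in all_traj) {
      id <- tr$subject[1]
      grp <- tr$group[1]
      dur <- tr$total_time[1]
      durations[[paste0(id, "-", trial)]] <- dur
      n_theta <- max(floor(dur * spec$theta_rate) + 1, 3)
      sim <- simulate_hmm_series(spec$hmm_truth[[grp]][[as.character(trial)]],
                                 n_theta,
                                 seed = sub_seed(spec$seed, paste0("theta-", id, "-", trial)))
      hidden[[paste0(id, "-", trial)]] <- sim$states
      theta[[paste0(id, "-", trial)]] <- tibble(
        subject = id, group = grp, trial = trial,
        time = (seq_len(n_theta) - 1) / spec$theta_rate,
        theta = sim$values)
    }
  }
  theta_df <- validate_theta(dplyr::bind_rows(theta))
  coords_df <- validate_trajectories(dplyr::bind_rows(coords), dt = spec$traj_dt)
  log_stage("simulated cohort: %d subjects x 2 trials (%d theta rows, %d coord rows)",
            2 * spec$n_per_group, nrow(theta_df), nrow(coords_df))
  list(theta = theta_df, coords = coords_df,
       truth = list(spec = spec, hidden_states = hidden, durations = durations))
}
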