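#' Behavioural features of a single trajectory
#'
#' Vector-level building blocks for the four coordinate-based features.
#' `step_headings()` returns the heading (four-quadrant arctangent, radians)
#' of each step; zero-displacement steps have undefined heading (`NA`).
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @name trajectory-primitives
#' @keywords internal
step_headings <- function(x, y) {
  dx <- diff(x); dy <- diff(y)
  h <- atan2(dy, dx)
  h[dx == 0 & dy == 0] <- NA_real_
  h
}

#' Total idle time of a trajectory
#'
#' Time the subject did not move: the sum of 0.25 s step durations whose
#' Euclidean displacement is at most `eps`.
#'
#' @param x,y Coordinate vectors sampled every `dt` seconds.
#' @param eps Displacement tolerance in Virtual Metres below which a step
#'   counts as idle (default 0: exact non-movement).
#' @param dt Sampling interval, seconds.
#' @return Idle time in seconds.
#' @export
total_idle_time <- function(x, y, eps = 0, dt = 0.25) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  disp <- sqrt(diff(x)^2 + diff(y)^2)
  sum(disp <= eps) * dt
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean step displacements, in Virtual Metres.
#'
#' @inheritParams total_idle_time
#' @return Path length in Virtual Metres.
#' @export
total_path_length <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Total angle shift of a trajectory
#'
#' Sum of absolute differences between consecutive step headings, in
#' degrees. Headings use the four-quadrant arctangent (`atan2`), so vertical
#' steps and opposite directions are handled unambiguously; each absolute
#' heading difference is wrapped to `[0, 180]` degrees so a turn and its
#' reverse count equally. Zero-displacement steps have no heading and are
#' skipped; consecutive headings are compared across them.
#'
#' @inheritParams total_idle_time
#' @return Total angle shift in degrees.
#' @export
total_angle_shift <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  h <- step_headings(x, y)
  h <- h[!is.na(h)]
  if (length(h) < 2) {
    abort("total_angle_shift needs at least two moving steps",
          class = "thetanav_degenerate_input")
  }
  d <- abs(diff(h))
  d <- pmin(d, 2 * pi - d) # wrap to [0, pi]
  sum(d) * 180 / pi
}

#' Average speed of a trajectory
#'
#' Total path length divided by the time to find the target (the trial's
#' total time; identical to the time-matched duration for non-learners).
#'
#' @inheritParams total_idle_time
#' @param total_time Trial duration in seconds.
#' @return Average speed in Virtual Metres per second.
#' @export
average_speed <- function(x, y, total_time) {
  if (!is.finite(total_time) || total_time <= 0) {
    abort("average_speed needs a positive total time", class = "thetanav_degenerate_input")
  }
  total_path_length(x, y) / total_time
}

#' Compute the four behavioural features per subject and trial
#'
#' Summarises a long trajectory table into one row per `(subject, trial)`
#' with the four engineered features: `total_idle_time` (s),
#' `total_path_length` (Vm), `total_angle_shift` (degrees) and
#' `average_speed` (Vm/s).
#'
#' @param coords A `trajectory_df` tibble (see [read_coordinates_csv()]).
#' @param eps Idle displacement tolerance, Virtual Metres.
#' @return A tibble with one row per subject and trial.
#' @export
trajectory_features <- function(coords, eps = 0) {
  out <- coords |>
    dplyr::summarise(
      group = .data$group[1],
      total_idle_time = total_idle_time(.data$x, .data$y, eps = eps),
      total_path_length = total_path_length(.data$x, .data$y),
      total_angle_shift = total_angle_shift(.data$x, .data$y),
      average_speed = average_speed(.data$x, .data$y, .data$total_time[1]),
      .by = c("subject", "trial")
    )
  log_stage("trajectory features: %d subject-trials x 4 features", nrow(out))
  out
}
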