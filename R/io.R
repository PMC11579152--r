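#' Default column names for the tabular inputs
#'
#' Input CSVs are plain header-ed tables; the mapping from the package's
#' canonical column names to the file's own headers is configurable here.
#'
#' @param subject,group,trial,time,theta,x,y,total_time Column names in the
#'   file for each canonical field.
#' @return Named list of column names.
#' @export
theta_cols <- function(subject = "subject", group = "group", trial = "trial",
                       time = "time", theta = "theta", x = "x", y = "y",
                       total_time = "total_time") {
  list(subject = subject, group = group, trial = trial, time = time,
       theta = theta, x = x, y = y, total_time = total_time)
}

read_input_csv <- function(path, cols, needed) {
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path), class = "thetanav_format_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("cannot parse CSV %s: %s", path, conditionMessage(e)),
                              class = "thetanav_format_error")
  )
  if (nrow(df) == 0) {
    abort(sprintf("input file %s is empty", path), class = "thetanav_format_error")
  }
  missing <- setdiff(unlist(cols[needed]), names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing column(s) in %s: %s", path, paste(missing, collapse = ", ")),
          class = "thetanav_format_error")
  }
  out <- df[unlist(cols[needed])]
  names(out) <- needed
  out
}

normalise_group <- function(group) {
  g <- gsub("[ -]", "_", tolower(as.character(group)))
  bad <- setdiff(unique(g), c("learner", "non_learner"))
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s (expected learner/non_learner)",
                  paste(bad, collapse = ", ")), class = "thetanav_validation_error")
  }
  g
}

normalise_trial <- function(trial) {
  tr <- suppressWarnings(as.integer(as.character(trial)))
  bad <- setdiff(unique(tr), c(1L, 12L))
  if (length(bad) > 0 || anyNA(tr)) {
    abort("trial labels must be 1 or 12", class = "thetanav_validation_error")
  }
  tr
}

#' Read theta-power time series from CSV
#'
#' Reads a long table with one row per time point of a subject's
#' frontal-midline theta-power trace, validates it, and returns a tibble with
#' canonical columns `subject`, `group`, `trial`, `time`, `theta`, sorted by
#' time within each subject and trial. One `(subject, trial)` pair is one
#' series; series may have different lengths (learner trials end when the
#' goal is found, non-learner trials are time-matched).
#'
#' @param path Path to a CSV file with a header.
#' @param cols Column-name mapping from [theta_cols()].
#' @return A tibble of class `theta_df`.
#' @export
read_theta_csv <- function(path, cols = theta_cols()) {
  df <- read_input_csv(path, cols, c("subject", "group", "trial", "time", "theta"))
  out <- validate_theta(df)
  log_stage("read %d theta series (%d rows) from %s",
            nrow(dplyr::distinct(out, .data$subject, .data$trial)), nrow(out), path)
  out
}

#' Validate a theta-series table
#'
#' Checks the invariants of the theta input: no missing values, at least 3
#' points per subject-trial series, strictly increasing times, recognised
#' group and trial labels. Returns the table sorted by subject, trial, time.
#'
#' @param df Data frame with columns `subject`, `group`, `trial`, `time`,
#'   `theta`.
#' @return The validated tibble (class `theta_df`).
#' @export
validate_theta <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("subject", "group", "trial", "time", "theta") %in% names(df)))
  if (anyNA(df[c("subject", "group", "trial", "time", "theta")])) {
    abort("theta table contains missing values", class = "thetanav_validation_error")
  }
  df$subject <- as.character(df$subject)
  df$group <- normalise_group(df$group)
  df$trial <- normalise_trial(df$trial)
  df <- dplyr::arrange(df, .data$subject, .data$trial, .data$time)
  chk <- df |>
    dplyr::summarise(
      n = dplyr::n(),
      mono = all(diff(.data$time) > 0),
      one_group = dplyr::n_distinct(.data$group) == 1,
      .by = c("subject", "trial")
    )
  if (any(chk$n < 3)) {
    bad <- chk$subject[chk$n < 3]
    abort(sprintf("theta series too short (< 3 points) for subject(s): %s",
                  paste(unique(bad), collapse = ", ")),
          class = "thetanav_validation_error")
  }
  if (!all(chk$mono)) {
    bad <- chk$subject[!chk$mono]
    abort(sprintf("non-increasing time within series for subject(s): %s",
                  paste(unique(bad), collapse = ", ")),
          class = "thetanav_validation_error")
  }
  if (!all(chk$one_group)) {
    abort("a subject maps to more than one group label",
          class = "thetanav_validation_error")
  }
  class(df) <- c("theta_df", class(df))
  df
}

#' Read navigation trajectories from CSV
#'
#' Reads a long table of arena x-y positions sampled every 0.25 s, one row
#' per time point per subject and trial, and validates the sampling grid.
#' If the file carries a `total_time` column it is kept (non-learner trials
#' are time-matched so total time can exceed the last recorded sample);
#' otherwise total time defaults to the last time stamp.
#'
#' @inheritParams read_theta_csv
#' @return A tibble of class `trajectory_df` with columns `subject`, `group`,
#'   `trial`, `time`, `x`, `y`, `total_time`.
#' @export
read_coordinates_csv <- function(path, cols = theta_cols()) {
  needed <- c("subject", "group", "trial", "time", "x", "y")
  have_tt <- cols$total_time %in% names(readr::read_csv(path, n_max = 0,
                                                        show_col_types = FALSE))
  if (have_tt) needed <- c(needed, "total_time")
  df <- read_input_csv(path, cols, needed)
  out <- validate_trajectories(df)
  log_stage("read %d trajectories (%d rows) from %s",
            nrow(dplyr::distinct(out, .data$subject, .data$trial)), nrow(out), path)
  out
}

#' Validate a trajectory table
#'
#' Checks the trajectory invariants: at least 3 points per series, times on
#' an equally spaced 0.25 s grid (tolerance 1e-9), no missing values, and
#' `total_time` at least the last time stamp.
#'
#' @param df Data frame with columns `subject`, `group`, `trial`, `time`,
#'   `x`, `y` and optionally `total_time`.
#' @param dt Expected sampling interval in seconds.
#' @return The validated tibble (class `trajectory_df`).
#' @export
validate_trajectories <- function(df, dt = 0.25) {
  df <- as_tibble(df)
  stopifnot(all(c("subject", "group", "trial", "time", "x", "y") %in% names(df)))
  core <- c("subject", "group", "trial", "time", "x", "y")
  if (anyNA(df[core])) {
    abort("trajectory table contains missing values", class = "thetanav_validation_error")
  }
  df$subject <- as.character(df$subject)
  df$group <- normalise_group(df$group)
  df$trial <- normalise_trial(df$trial)
  df <- dplyr::arrange(df, .data$subject, .data$trial, .data$time)
  if (!"total_time" %in% names(df)) {
    df <- dplyr::mutate(df, total_time = max(.data$time), .by = c("subject", "trial"))
  }
  chk <- df |>
    dplyr::summarise(
      n = dplyr::n(),
      grid = all(abs(diff(.data$time) - dt) <= 1e-9),
      tt_ok = .data$total_time[1] >= max(.data$time) - 1e-9,
      .by = c("subject", "trial")
    )
  if (any(chk$n < 3)) {
    abort(sprintf("trajectory too short (< 3 points) for subject(s): %s",
                  paste(unique(chk$subject[chk$n < 3]), collapse = ", ")),
          class = "thetanav_validation_error")
  }
  if (!all(chk$grid)) {
    abort(sprintf("irregular %g s sampling for subject(s): %s", dt,
                  paste(unique(chk$subject[!chk$grid]), collapse = ", ")),
          class = "thetanav_validation_error")
  }
  if (!all(chk$tt_ok)) {
    abort("total_time is smaller than the last recorded time",
          class = "thetanav_validation_error")
  }
  class(df) <- c("trajectory_df", class(df))
  df
}

#' Write theta series / trajectories to CSV
#'
#' Plain-CSV writers that round-trip losslessly with the readers.
#'
#' @param df Table as returned by [read_theta_csv()] / [read_coordinates_csv()]
#'   (or the simulator).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_theta_csv <- function(df, path) {
  readr::write_csv(as_tibble(df)[c("subject", "group", "trial", "time", "theta")], path)
  invisible(path)
}

#' @rdname write_theta_csv
#' @export
write_coordinates_csv <- function(df, path) {
  keep <- c("subject", "group", "trial", "time", "x", "y", "total_time")
  readr::write_csv(as_tibble(df)[intersect(keep, names(df))], path)
  invisible(path)
}
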