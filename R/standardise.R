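#' Min-max rescaling of a value sequence
#'
#' Rescales a series to `[0, 1]` via `(x - min(x)) / (max(x) - min(x))`, so
#' the minimum maps to 0 and the maximum to 1. Applied per series (per
#' subject and trial), never pooled across subjects.
#'
#' @param x Numeric vector, length >= 2, not constant.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' minmax_scale(c(0, 5, 10))
minmax_scale <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2 || anyNA(x)) {
    abort("minmax_scale needs >= 2 non-missing values", class = "thetanav_degenerate_input")
  }
  rng <- range(x)
  if (rng[2] <= rng[1]) {
    abort("minmax_scale is undefined for a constant series (max == min)",
          class = "thetanav_degenerate_input")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Z-score rescaling of a value sequence
#'
#' Centres and scales a series to sample mean 0 and sample standard
#' deviation 1, using the n-1 denominator.
#'
#' @param x Numeric vector, length >= 2, with positive sample SD.
#' @return Numeric vector with mean 0 and SD 1.
#' @export
#' @examples
#' zscore_scale(c(1, 2, 3))
zscore_scale <- function(x) {
  stopifnot(is.numeric(x))
  if (length(x) < 2 || anyNA(x)) {
    abort("zscore_scale needs >= 2 non-missing values", class = "thetanav_degenerate_input")
  }
  s <- sd(x)
  if (!is.finite(s) || s <= 0) {
    abort("zscore_scale is undefined for a zero-variance series",
          class = "thetanav_degenerate_input")
  }
  (x - mean(x)) / s
}

#' Standardise theta series per subject and trial
#'
#' Applies one of the supported rescalings to the `theta` column of a long
#' theta table, independently within each `(subject, trial)` series. `"raw"`
#' leaves the values untouched. Per-series scaling matches the leave-one-out
#' evaluation setting: no statistic is shared across subjects.
#'
#' @param theta A `theta_df` tibble (see [read_theta_csv()]).
#' @param method One of `"raw"`, `"minmax"`, `"zscore"`.
#' @return The input tibble with `theta` replaced by its standardised values
#'   and a `scale` column recording the method.
#' @export
standardise_theta <- function(theta, method = c("raw", "minmax", "zscore")) {
  method <- match.arg(method)
  f <- switch(method, raw = identity, minmax = minmax_scale, zscore = zscore_scale)
  out <- theta |>
    dplyr::mutate(theta = f(.data$theta), .by = c("subject", "trial")) |>
    dplyr::mutate(scale = method)
  class(out) <- unique(c("theta_df", class(out)))
  out
}
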