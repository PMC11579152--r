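#' Detect peaks in a series
#'
#' A peak is a strict interior local maximum: an index `k` (2..T-1 in R's
#' 1-based indexing) with `x[k-1] < x[k] > x[k+1]`. A flat plateau whose
#' neighbouring values are both lower counts once, at its first index.
#' Each peak is returned with its height `x[k]` and its curvature, the
#' second-order difference `x[k-1] - 2 x[k] + x[k+1]` (negative at a strict
#' maximum).
#'
#' @param x Numeric series of length >= 3.
#' @return A tibble with columns `index`, `height`, `curvature`; zero rows
#'   when the series has no peaks.
#' @export
#' @examples
#' detect_peaks(c(0, 1, 0, 2, 0))
detect_peaks <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3)
  r <- rle(x)
  nr <- length(r$values)
  first_idx <- cumsum(c(1, r$lengths[-nr]))
  is_peak <- logical(nr)
  if (nr >= 3) {
    inner <- 2:(nr - 1)
    is_peak[inner] <- r$values[inner] > r$values[inner - 1] &
      r$values[inner] > r$values[inner + 1]
  }
  idx <- first_idx[is_peak]
  tibble(index = idx,
         height = x[idx],
         curvature = vapply(idx, function(k) peak_curvature(x, k), numeric(1)))
}

#' Curvature at a series index
#'
#' Second-order difference `x[k-1] - 2 x[k] + x[k+1]` at an interior index
#' `k`; at a strict local maximum this is negative, and its magnitude
#' measures how sharp the peak is.
#'
#' @param x Numeric series.
#' @param k Interior index (1-based; `2 <= k <= length(x) - 1`).
#' @return The curvature value.
#' @export
#' @examples
#' peak_curvature(c(2, 5, 3), 2) # -5
peak_curvature <- function(x, k) {
  if (k < 2 || k > length(x) - 1) {
    abort("curvature needs an interior index (2 <= k <= length(x) - 1)",
          class = "thetanav_index_error")
  }
  x[k - 1] - 2 * x[k] + x[k + 1]
}

#' Peak table for every series of a cohort
#'
#' Runs [detect_peaks()] on each `(subject, trial)` theta series and stacks
#' the results.
#'
#' @param theta A (standardised) `theta_df` tibble.
#' @return A tibble with columns `subject`, `group`, `trial`, `index`,
#'   `height`, `curvature`.
#' @export
peak_table <- function(theta) {
  out <- theta |>
    dplyr::reframe(detect_peaks(.data$theta), .by = c("subject", "group", "trial"))
  log_stage("peak detection: %d peaks across %d series", nrow(out),
            nrow(dplyr::distinct(theta, .data$subject, .data$trial)))
  out
}
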