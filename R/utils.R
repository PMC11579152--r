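#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from a single integer seed. Each
#' pipeline stage draws from its own substream, obtained by hashing the
#' master seed together with a stream label, so that e.g. adding classifier
#' restarts never perturbs the simulated cohort.
#'
#' @param seed Master integer seed.
#' @param stream Character label of the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  # small multiplicative string hash, kept inside 31 bits
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' One-line stage log
#'
#' Emits a single `message()` per pipeline stage with basic counts so runs
#' can be audited; silenced with `options(thetanav.quiet = TRUE)`.
#' @keywords internal
log_stage <- function(...) {
  if (!isTRUE(getOption("thetanav.quiet", FALSE))) {
    message("[thetanav] ", sprintf(...))
  }
  invisible(NULL)
}

# shared validators ----------------------------------------------------------

assert_prob_matrix <- function(P, tol = 1e-10) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    abort("transition matrix must be square", class = "thetanav_validation_error")
  }
  if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol)) {
    abort("transition matrix rows must be non-negative and sum to 1",
          class = "thetanav_validation_error")
  }
  invisible(P)
}

assert_prob_vector <- function(p, tol = 1e-10) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    abort("probability vector must be non-negative and sum to 1",
          class = "thetanav_validation_error")
  }
  invisible(p)
}
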