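# Shared small helpers.

#' Round half up
#'
#' Commercial rounding: 0.5 always rounds away from zero (for the
#' non-negative counts used throughout the sampling design). Base R's
#' `round()` rounds half to even, which is not what a "round N% of the
#' species" sampling rule means.
#'
#' @param x numeric vector, non-negative.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: stage k of a run seeded with `seed` uses
#' `(seed + 10007L * k) mod (2^31 - 1)`. 10007 is prime so distinct stages
#' of the same run never collide for k < 2^31/10007.
#'
#' @param seed master seed (integer).
#' @param k stage counter (non-negative integer).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(k)) %% 2147483647)
}

stop_bp <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
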