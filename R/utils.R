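#' Derive a stage-specific seed from a master seed
#'
#' Fans a single pipeline seed out to per-stage seeds so that stages are
#' individually reproducible without sharing an RNG stream. The stage name is
#' hashed with a small rolling polynomial and folded into the master seed,
#' keeping the result a valid 32-bit R integer.
#'
#' @param seed master integer seed
#' @param stage character scalar naming the stage
#' @return an integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Round half-away-from-zero and clamp to an integer range
#'
#' Rounding is half-away-from-zero (0.5 -> 1, -0.5 -> -1), not banker's
#' rounding, so the +1/-1 phenotype encoding is treated symmetrically.
#' Rounded values are then clamped to `[lo, hi]`.
#'
#' @param values finite numeric vector
#' @param lo,hi inclusive integer bounds (defaults -4, +4)
#' @return integer vector with every element in `[lo, hi]`
#' @examples
#' round_and_cap(c(0.5, -0.5, 4.7, 2))
#' @export
round_and_cap <- function(values, lo = -4L, hi = 4L) {
  if (lo > hi) stop("`lo` must not exceed `hi`")
  if (any(!is.finite(values))) stop("`values` must be finite")
  r <- sign(values) * floor(abs(values) + 0.5)
  as.integer(pmin(pmax(r, lo), hi))
}

msg <- function(...) message("[exomehub] ", sprintf(...))
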