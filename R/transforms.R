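# Dynamic-range compression of fluence volumes and the dual-gain inference
# merge.  All transforms run in double precision: at gain c = 1e7 a
# single-precision log/exp round trip loses significant digits.

#' Logarithmic dynamic-range compression of a fluence volume
#'
#' Applies \code{y = ln(c * x + 1)} element-wise.  The +1 guarantees a
#' non-negative output; the gain \code{c} controls how strongly small
#' fluence values are amplified before compression.
#'
#' @param x a \code{fluence_volume} or non-negative numeric array
#' @param c positive gain constant
#' @return numeric array of the same shape (the CNN's working
#'   representation)
#' @export
forward_log <- function(x, c = 1) {
  stopifnot(c > 0)
  v <- if (inherits(x, "fluence_volume")) x$values else x
  neg <- which(v < 0)
  if (length(neg))
    stop("negative fluence at voxel index ", neg[1],
         " (fluence must be non-negative)")
  log1p(c * v)
}

#' Invert the logarithmic compression
#'
#' Applies \code{x = (exp(y) - 1) / c}.  Small negative inputs (a denoiser
#' may overshoot slightly) are clamped to zero with a warning.
#'
#' @param y non-negative numeric array in log space
#' @param c positive gain constant used in the forward transform
#' @return numeric array of fluence values
#' @export
inverse_log <- function(y, c = 1) {
  stopifnot(c > 0)
  if (any(y < 0)) {
    warning("negative log-space values clamped to 0 before inversion")
    y <- pmax(y, 0)
  }
  expm1(y) / c
}

#' Construct a dual-gain merge policy
#'
#' @param threshold fluence threshold (pre-transform) separating the
#'   high-value pass from the low-value pass; default 0.03
#' @param low_gain gain for voxels above the threshold; default 1
#' @param high_gain gain for voxels at or below the threshold; default 1e7
#' @export
merge_policy <- function(threshold = 0.03, low_gain = 1, high_gain = 1e7) {
  stopifnot(threshold > 0, low_gain > 0, high_gain > low_gain)
  structure(list(threshold = threshold, low_gain = low_gain,
                 high_gain = high_gain), class = "merge_policy")
}

#' Dual-gain denoising of a fluence volume
#'
#' Denoises two copies of the input, one log-compressed with the low gain
#' and one with the high gain, inverts both, and merges voxel-wise: voxels
#' whose ORIGINAL fluence exceeds the policy threshold take the low-gain
#' result, all others the high-gain result.  This widens the usable dynamic
#' range of a denoiser trained on log-compressed data.
#'
#' @param x a \code{fluence_volume} or non-negative array
#' @param model a trained \code{mc_denoiser} (or any function mapping a
#'   log-space array to a log-space array)
#' @param policy a \code{\link{merge_policy}}
#' @return denoised volume as a numeric array (same shape), all values >= 0
#' @export
dual_gain_denoise <- function(x, model, policy = merge_policy()) {
  v <- if (inherits(x, "fluence_volume")) x$values else x
  apply_model <- function(y) {
    if (is.function(model)) model(y) else denoise_volume(model, y)
  }
  out1 <- inverse_log(pmax(apply_model(forward_log(v, policy$low_gain)), 0),
                      policy$low_gain)
  out2 <- inverse_log(pmax(apply_model(forward_log(v, policy$high_gain)), 0),
                      policy$high_gain)
  sel <- v > policy$threshold
  out <- out2
  out[sel] <- out1[sel]
  out
}
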