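# Global (MSE / 3D SSIM / PSNR) and local (voxel SNR, SNR improvement,
# photon multiplier) evaluation metrics.  Global metrics are computed on
# log-compressed volumes: the PSNR ceiling Imax = 40 is defined on the
# transformed scale, and that is also the scale the denoisers operate in.

as_vol <- function(x) if (inherits(x, "fluence_volume")) x$values else x

#' Mean squared / absolute error between two volumes
#' @param x,y numeric arrays of identical shape (log-space by convention)
#' @export
mse <- function(x, y) {
  x <- as_vol(x); y <- as_vol(y)
  if (!identical(dim(x), dim(y))) stop("volume shapes differ")
  mean((x - y)^2)
}

#' @rdname mse
#' @export
mae <- function(x, y) {
  x <- as_vol(x); y <- as_vol(y)
  if (!identical(dim(x), dim(y))) stop("volume shapes differ")
  mean(abs(x - y))
}

#' Parameters of the 3D structural similarity metric
#'
#' @param sigma Gaussian window standard deviation in voxels (default 5)
#' @param data_range dynamic range L of the compared volumes; the
#'   stabilizing constants are \code{C1 = (0.01 L)^2}, \code{C2 = (0.03
#'   L)^2}
#' @export
ssim_params <- function(sigma = 5, data_range = 40) {
  stopifnot(sigma > 0, data_range > 0)
  list(sigma = sigma, C1 = (0.01 * data_range)^2,
       C2 = (0.03 * data_range)^2)
}

gaussian_kernel_1d <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

gauss3d <- function(x, kernel) {
  out <- .gauss_blur3d_cpp(as.numeric(x), dim(x), kernel)
  array(out, dim(x))
}

#' 3D structural similarity index
#'
#' Local means, variances and covariance are estimated by convolving both
#' volumes with a truncated, renormalized 3D Gaussian window (reflective
#' border padding); the per-voxel structural similarity is averaged over
#' the volume.  Identical volumes score exactly 1.
#'
#' @param x,y numeric arrays of identical shape
#' @param params list from \code{\link{ssim_params}}
#' @return scalar SSIM, at most 1
#' @export
ssim3d <- function(x, y, params = ssim_params()) {
  x <- as_vol(x); y <- as_vol(y)
  if (!identical(dim(x), dim(y))) stop("volume shapes differ")
  k <- gaussian_kernel_1d(params$sigma)
  mx <- gauss3d(x, k); my <- gauss3d(y, k)
  vx <- gauss3d(x * x, k) - mx^2
  vy <- gauss3d(y * y, k) - my^2
  cxy <- gauss3d(x * y, k) - mx * my
  ssim_map <- ((2 * mx * my + params$C1) * (2 * cxy + params$C2)) /
    ((mx^2 + my^2 + params$C1) * (vx + vy + params$C2))
  mean(ssim_map)
}

#' Peak signal-to-noise ratio
#'
#' \code{20 log10(Imax / RMSE(x, y))} with the peak \code{i_max} defined on
#' the log-transformed scale (default 40).  Identical volumes yield
#' \code{Inf} with a warning.
#'
#' @param x,y numeric arrays of identical shape
#' @param i_max peak value on the transformed scale
#' @return PSNR in dB
#' @export
psnr <- function(x, y, i_max = 40) {
  x <- as_vol(x); y <- as_vol(y)
  if (!identical(dim(x), dim(y))) stop("volume shapes differ")
  rmse <- sqrt(mean((x - y)^2))
  if (rmse == 0) {
    warning("identical volumes: PSNR is infinite")
    return(Inf)
  }
  20 * log10(i_max / rmse)
}

#' Voxel-wise SNR map from a repetition stack
#'
#' For a stack of independently seeded repetitions, computes the per-voxel
#' mean and population standard deviation (1/N) and reports \code{SNR(r) =
#' 20 log10(mu(r) / sigma(r))} in dB.  Voxels with zero mean or zero
#' spread are excluded from the validity mask.
#'
#' @param stack list of \code{fluence_volume}s or 3D arrays (N >= 2,
#'   identical shapes)
#' @return object of class \code{snr_map}: \code{values} (dB, NA where
#'   undefined), \code{mask} (validity), \code{mean}, \code{sd},
#'   \code{n_reps}
#' @export
snr_map <- function(stack) {
  if (length(stack) < 2) stop("at least 2 repetitions are required")
  vols <- lapply(stack, as_vol)
  dm <- dim(vols[[1]])
  for (v in vols)
    if (!identical(dim(v), dm)) stop("repetition shapes differ")
  n <- length(vols)
  s1 <- array(0, dm); s2 <- array(0, dm)
  for (v in vols) { s1 <- s1 + v; s2 <- s2 + v * v }
  mu <- s1 / n
  sig <- sqrt(pmax(0, s2 / n - mu^2))
  mask <- mu > 0 & sig > 0
  vals <- array(NA_real_, dm)
  vals[mask] <- 20 * log10(mu[mask] / sig[mask])
  structure(list(values = vals, mask = mask, mean = mu, sd = sig,
                 n_reps = n), class = "snr_map")
}

#' SNR improvement between two SNR maps
#'
#' \code{delta_snr_all} averages (after - before) over voxels valid in
#' both maps; \code{delta_snr_eff} averages over the effective region where
#' the improvement exceeds \code{eff_threshold_db} (default 0.5 dB), and is
#' \code{NA} when that region is empty.
#'
#' @param before,after \code{\link{snr_map}} objects of identical shape
#' @param eff_threshold_db effective-region threshold in dB
#' @return list with \code{delta_snr_all}, \code{delta_snr_eff},
#'   \code{n_voxels}, \code{n_effective}
#' @export
delta_snr <- function(before, after, eff_threshold_db = 0.5) {
  stopifnot(inherits(before, "snr_map"), inherits(after, "snr_map"))
  if (!identical(dim(before$values), dim(after$values)))
    stop("SNR map shapes differ")
  common <- before$mask & after$mask
  if (!any(common)) stop("no commonly valid voxels between the SNR maps")
  d <- after$values[common] - before$values[common]
  eff <- d > eff_threshold_db
  list(delta_snr_all = mean(d),
       delta_snr_eff = if (any(eff)) mean(d[eff]) else NA_real_,
       n_voxels = sum(common), n_effective = sum(eff))
}

#' Equivalent photon-number multiplier
#'
#' \code{MF = 10^(dSNR / 10)}: the factor by which the simulated photon
#' count would have to grow to match the measured SNR improvement, under
#' shot-noise scaling (10 dB per tenfold photons).  A 20 dB improvement is
#' equivalent to 100x more photons.
#'
#' @param delta_snr_db SNR improvement in dB
#' @export
photon_multiplier <- function(delta_snr_db) {
  stopifnot(all(is.finite(delta_snr_db)))
  10^(delta_snr_db / 10)
}

#' Bundle global and local metrics into one report
#'
#' @param clean,noisy_or_denoised log-space arrays for the global metrics
#' @param before,after optional \code{snr_map}s for the local metrics
#' @param metadata named list recorded verbatim
#' @return object of class \code{metrics_report}; when an SNR improvement
#'   is present, \code{mf} always equals
#'   \code{photon_multiplier(delta_snr_all)}
#' @export
metrics_report <- function(clean, noisy_or_denoised, before = NULL,
                           after = NULL, metadata = list()) {
  rep <- list(mse = mse(noisy_or_denoised, clean),
              ssim = ssim3d(noisy_or_denoised, clean),
              psnr = psnr(noisy_or_denoised, clean),
              metadata = metadata)
  if (!is.null(before) && !is.null(after)) {
    ds <- delta_snr(before, after)
    rep$delta_snr_all <- ds$delta_snr_all
    rep$delta_snr_eff <- ds$delta_snr_eff
    rep$mf <- photon_multiplier(ds$delta_snr_all)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Denoising metrics report\n")
  cat(sprintf("  MSE  (log space): %.6g\n", x$mse))
  cat(sprintf("  SSIM (3D)       : %.6g\n", x$ssim))
  cat(sprintf("  PSNR            : %.6g dB\n", x$psnr))
  if (!is.null(x$delta_snr_all)) {
    cat(sprintf("  dSNR (all)      : %.4f dB\n", x$delta_snr_all))
    cat(sprintf("  dSNR (effective): %.4f dB\n", x$delta_snr_eff))
    cat(sprintf("  photon multiplier MF: %.4f\n", x$mf))
  }
  invisible(x)
}

#' Mean and SNR profile along an axis-aligned line
#'
#' Extracts, along the free axis of an axis-aligned line through the
#' volume, the per-voxel repetition mean and SNR.  Used for unbiasedness
#' checks: a well-behaved denoiser leaves the mean profile unchanged while
#' raising the SNR profile.
#'
#' @param stack list of \code{fluence_volume}s/arrays (the repetition
#'   stack)
#' @param axis free axis of the line (1, 2 or 3)
#' @param fixed named or positional length-2 integer vector giving the
#'   voxel indices held fixed on the other two axes
#' @return data.frame with columns \code{position}, \code{mean},
#'   \code{snr}
#' @export
cross_section_profile <- function(stack, axis = 3, fixed) {
  sm <- snr_map(stack)
  dm <- dim(sm$mean)
  others <- setdiff(1:3, axis)
  if (length(fixed) != 2 || any(fixed < 1) || any(fixed > dm[others]))
    stop("fixed indices fall outside the volume")
  idx <- list(fixed[1], fixed[2])
  sel <- vector("list", 3)
  sel[[axis]] <- seq_len(dm[axis])
  sel[[others[1]]] <- fixed[1]
  sel[[others[2]]] <- fixed[2]
  data.frame(position = seq_len(dm[axis]),
             mean = as.numeric(sm$mean[sel[[1]], sel[[2]], sel[[3]]]),
             snr = as.numeric(sm$values[sel[[1]], sel[[2]], sel[[3]]]))
}

#' @export
plot.snr_map <- function(x, slice = NULL, ...) {
  dm <- dim(x$values)
  if (is.null(slice)) slice <- ceiling(dm[3] / 2)
  image(x$values[, , slice], main = sprintf("voxel SNR (dB), slice %d", slice),
        col = gray(seq(0, 1, length.out = 64)), ...)
  invisible(x)
}
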