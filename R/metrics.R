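#' Mean signal-to-noise ratio of a region of interest
#'
#' `MSNR = mean(volume[roi]) / sd(volume[noise_roi])`: the ROI mean divided
#' by the standard deviation of a large region outside it.  Standard
#' deviations use the population (n) denominator.
#'
#' @param volume numeric 3D array.
#' @param roi logical mask or integer index vector selecting the signal ROI.
#' @param noise_roi mask/indices of the noise reference region.
#' @return scalar MSNR.
#' @export
compute_msnr <- function(volume, roi, noise_roi) {
  mu <- mean(volume[roi])
  nz <- volume[noise_roi]
  s <- sqrt(mean((nz - mean(nz))^2))
  if (s == 0) stop("noise region has zero standard deviation")
  mu / s
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' `CNR = |MSNR(roi1) - MSNR(roi2)|` with both MSNRs referred to the same
#' noise region.
#'
#' @inheritParams compute_msnr
#' @param roi1,roi2 the two signal ROIs.
#' @return scalar CNR.
#' @export
compute_cnr <- function(volume, roi1, roi2, noise_roi) {
  abs(compute_msnr(volume, roi1, noise_roi) -
        compute_msnr(volume, roi2, noise_roi))
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB between a reference and a test volume of
#' equal shape.  Identical volumes return `Inf`.
#'
#' @param reference,test numeric arrays of equal shape.
#' @param peak positive peak intensity (defaults to `max(reference)`).
#' @return scalar PSNR in dB.
#' @export
compute_psnr <- function(reference, test, peak = max(reference)) {
  if (!identical(dim(reference), dim(test))) stop("shape mismatch")
  if (peak <= 0) stop("peak must be positive")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}
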