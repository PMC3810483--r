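#' Wavelet-domain noise model
#'
#' Describes the additive noise assumed on the complex wavelet coefficients:
#' either white Gaussian or two-sided Rayleigh.  The two parameterizations
#' are locked together by `sigma_n^2 = 2 alpha^2` (the two-sided Rayleigh
#' variance), so supplying either determines the other.
#'
#' @param kind `"gaussian"` or `"two_sided_rayleigh"`.
#' @param sigma_n wavelet-domain noise standard deviation (> 0), or `NULL`
#'   if `alpha` is given.
#' @param alpha two-sided Rayleigh parameter (> 0), or `NULL` if `sigma_n`
#'   is given.
#' @return object of class `noise_model` with fields `kind`, `sigma_n`,
#'   `alpha`.
#' @export
noise_model <- function(kind = c("gaussian", "two_sided_rayleigh"),
                        sigma_n = NULL, alpha = NULL) {
  kind <- match.arg(kind)
  if (is.null(sigma_n) && is.null(alpha))
    stop("supply `sigma_n` or `alpha`")
  if (is.null(sigma_n)) sigma_n <- sqrt(2) * alpha
  if (is.null(alpha)) alpha <- sigma_n / sqrt(2)
  if (sigma_n <= 0) stop("noise scale must be positive")
  if (abs(sigma_n^2 - 2 * alpha^2) > 1e-8 * sigma_n^2)
    stop("inconsistent sigma_n/alpha: need sigma_n^2 = 2 alpha^2")
  structure(list(kind = kind, sigma_n = sigma_n, alpha = alpha),
            class = "noise_model")
}

#' Bivariate noise density
#'
#' Density of the parent-child noise pair `(n1, n2)`: an isotropic bivariate
#' Gaussian for `kind = "gaussian"`, or the separable two-sided Rayleigh
#' density `|n1 n2| / (4 alpha^4) exp(-(n1^2 + n2^2) / (2 alpha^2))`, which
#' vanishes on the coordinate axes and has per-axis variance `2 alpha^2`.
#'
#' @param n1,n2 evaluation points (vectorized).
#' @param model a [noise_model()].
#' @return density values.
#' @export
noise_pdf_bivariate <- function(n1, n2, model) {
  stopifnot(inherits(model, "noise_model"))
  if (model$kind == "gaussian") {
    s2 <- model$sigma_n^2
    exp(-(n1^2 + n2^2) / (2 * s2)) / (2 * pi * s2)
  } else {
    a <- model$alpha
    abs(n1 * n2) / (4 * a^4) * exp(-(n1^2 + n2^2) / (2 * a^2))
  }
}

#' Log / exponential intensity mapping for the homomorphic speckle model
#'
#' Forward: `log(volume + epsilon)`, turning the multiplicative speckle
#' model `x = s * g` into an additive one; inverse: `exp(volume) - epsilon`.
#' `epsilon` guards zero intensities; its default is 1 for integer-valued
#' volumes (count-like data) and `1e-6 * max(volume)` otherwise.
#'
#' @param volume numeric 3D array; must be nonnegative for the forward map.
#' @param direction `"forward"` or `"inverse"`.
#' @param epsilon positive offset; `NULL` for the default rule.
#' @return transformed volume (same shape); the chosen epsilon is attached
#'   as attribute `"epsilon"`.
#' @export
homomorphic_map <- function(volume, direction = c("forward", "inverse"),
                            epsilon = NULL) {
  direction <- match.arg(direction)
  if (is.null(epsilon)) {
    epsilon <- if (all(volume == round(volume))) 1
               else 1e-6 * max(abs(volume))
    if (epsilon <= 0) epsilon <- 1e-12
  }
  if (direction == "forward") {
    if (any(volume < 0)) stop("forward homomorphic map requires nonnegative input")
    out <- log(volume + epsilon)
  } else {
    out <- exp(volume) - epsilon
  }
  attr(out, "epsilon") <- epsilon
  out
}

#' Robust wavelet-domain noise level estimate
#'
#' The median absolute deviation rule
#' `sigma_n = median(|finest-scale coefficients|) / 0.6745`, by default
#' pooled over the real and imaginary parts of all 28 finest-scale
#' subbands, giving the single global `sigma_n` that the shrinkage
#' formulas assume.  Optionally returns one estimate per subband, or uses
#' coefficient moduli instead of the real/imaginary parts.
#'
#' @param pyramid a `complex_pyramid`.
#' @param per_subband if `TRUE`, return a length-28 vector.
#' @param use `"realimag"` (default) pools real and imaginary parts;
#'   `"modulus"` uses `|y|` (divided by the Rayleigh-median constant
#'   is *not* applied — this option is a diagnostic).
#' @return noise standard deviation estimate(s).
#' @export
estimate_noise_sigma <- function(pyramid, per_subband = FALSE,
                                 use = c("realimag", "modulus")) {
  stopifnot(inherits(pyramid, "complex_pyramid"))
  use <- match.arg(use)
  vals <- function(s) if (use == "realimag") c(abs(Re(s)), abs(Im(s)))
                      else Mod(s)
  finest <- pyramid$subbands[[1]]
  if (length(finest) == 0) stop("empty pyramid")
  if (per_subband) {
    vapply(finest, function(s) stats::median(vals(s)) / 0.6745, numeric(1))
  } else {
    stats::median(unlist(lapply(finest, vals))) / 0.6745
  }
}

#' Direct (non-homomorphic) speckle decomposition
#'
#' Applies the forward transform to raw speckled data, under the model
#' `W(x) = W(s) + W(s (g - 1))`: the second term is zero-mean and
#' uncorrelated with the first, so it is treated as additive wavelet-domain
#' noise whose global level is estimated by the MAD rule.
#'
#' @param volume nonnegative 3D array of speckled intensities.
#' @param levels number of transform scales.
#' @return list with `pyramid` and `sigma_n`.
#' @export
nonhomomorphic_decompose <- function(volume, levels = 3L) {
  pyr <- forward_dtcwt3d(volume, levels)
  list(pyramid = pyr, sigma_n = estimate_noise_sigma(pyr))
}
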