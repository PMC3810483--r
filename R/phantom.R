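#' Retina-like phantom specification
#'
#' Parameters of the synthetic study volume: horizontal intensity strata
#' stacked along axis 1 (the A-scan depth axis), one embedded hypo-intense
#' ellipsoidal lesion (a SEAD-like blob), and a background level.  The
#' default emulates a macular B-scan stack at a size where a full
#' denoising run completes in well under a minute: 128 x 128 x 32 voxels
#' with six layers and one lesion centred in the mid layers.
#'
#' @param shape integer 3-vector of extents (depth, lateral, B-scan index).
#' @param layers two-column matrix (or list of pairs) of layer
#'   `(thickness, intensity)` entries tiling the depth axis.
#' @param lesion list with `center` (3-vector), `semi_axes` (3-vector) and
#'   `intensity`.
#' @param seed integer seed recorded with the spec (the clean phantom is
#'   deterministic; the seed feeds the noise operators).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 32L),
                         layers = rbind(c(36, 30), c(12, 180), c(20, 120),
                                        c(12, 200), c(24, 90), c(24, 55)),
                         lesion = list(center = c(72, 64, 16),
                                       semi_axes = c(11, 20, 9),
                                       intensity = 40),
                         seed = 1L) {
  layers <- as.matrix(layers)
  if (sum(layers[, 1]) != shape[1])
    stop("layer thicknesses must tile the depth extent (axis 1)")
  if (any(layers[, 2] <= 0) || lesion$intensity <= 0)
    stop("intensities must be positive")
  if (any(lesion$center - lesion$semi_axes < 1) ||
      any(lesion$center + lesion$semi_axes > shape))
    stop("lesion must lie inside the grid")
  structure(list(shape = as.integer(shape), layers = layers,
                 lesion = lesion, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the layered phantom and its evaluation ROIs
#'
#' Builds the piecewise-constant layered volume with the embedded
#' ellipsoidal lesion and returns, alongside it, three pairwise disjoint
#' masks: `lesion` (the hypo-intense blob, signal ROI 1), `layer` (a box
#' inside the brightest stratum, signal ROI 2), and `noise` (a box in the
#' top background stratum used as the noise reference region).
#'
#' @param spec a [phantom_spec()].
#' @return list with `clean` (3D array) and `rois` (list of three logical
#'   masks).
#' @export
make_layered_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  depth_int <- rep(spec$layers[, 2], times = spec$layers[, 1])
  clean <- array(rep(depth_int, times = d[2] * d[3]), d)
  ctr <- spec$lesion$center
  ax <- spec$lesion$semi_axes
  z1 <- (seq_len(d[1]) - ctr[1]) / ax[1]
  z2 <- (seq_len(d[2]) - ctr[2]) / ax[2]
  z3 <- (seq_len(d[3]) - ctr[3]) / ax[3]
  rad <- outer(outer(z1^2, z2^2, `+`), z3^2, `+`)
  lesion_mask <- rad <= 1
  clean[lesion_mask] <- spec$lesion$intensity
  # brightest stratum, away from the lesion laterally
  bright <- which.max(spec$layers[, 2])
  zr <- cumsum(spec$layers[, 1])
  z0 <- if (bright == 1) 1 else zr[bright - 1] + 1
  layer_mask <- array(FALSE, d)
  lat <- seq_len(max(4, d[2] %/% 5))
  layer_mask[(z0 + 1):(zr[bright] - 1), lat, ] <- TRUE
  layer_mask <- layer_mask & !lesion_mask
  noise_mask <- array(FALSE, d)
  ntop <- max(4, spec$layers[1, 1] - 4)
  noise_mask[2:ntop, , ] <- TRUE
  noise_mask <- noise_mask & !lesion_mask & !layer_mask
  list(clean = clean,
       rois = list(lesion = lesion_mask, layer = layer_mask,
                   noise = noise_mask))
}

#' Apply unit-mean multiplicative speckle
#'
#' Multiplies the clean volume by i.i.d. unit-mean speckle `g` of the
#' requested standard deviation (`contrast`).  Two laws are offered:
#' `"rayleigh_sq"` draws `g = R^2 / E[R^2]` with `R` Rayleigh — the
#' squared-envelope model of fully developed speckle — and `"gamma"` draws
#' `g ~ Gamma(L, 1/L)` (multi-look speckle).  For each law the free
#' parameter is solved from `contrast`; `rayleigh_sq` has fixed unit
#' contrast, so it is mixed towards 1 (`g' = 1 + c (g - 1)`) for other
#' contrasts.
#'
#' @param clean positive 3D array.
#' @param law `"rayleigh_sq"` or `"gamma"`.
#' @param contrast target standard deviation of `g` (>= 0).
#' @param seed integer RNG seed.
#' @return speckled volume `clean * g`.
#' @export
apply_speckle <- function(clean, law = c("rayleigh_sq", "gamma"),
                          contrast = 0.5, seed = 1L) {
  law <- match.arg(law)
  if (any(clean <= 0)) stop("clean volume must be positive")
  if (contrast < 0) stop("contrast must be >= 0")
  if (contrast == 0) return(clean)
  set.seed(seed)
  n <- length(clean)
  g <- if (law == "rayleigh_sq") {
    r2 <- stats::rexp(n)               # squared Rayleigh envelope, mean 1
    1 + contrast * (r2 - 1)
  } else {
    L <- 1 / contrast^2
    stats::rgamma(n, shape = L, rate = L)
  }
  g <- pmax(g, 1e-6)
  clean * array(g, dim(clean))
}

#' Apply intensity-dependent additive Gaussian noise
#'
#' Nonstationary additive model: `x(i) = s(i) + n(i)` with independent
#' zero-mean Gaussian `n(i)` of standard deviation
#' `sigma_g(i) = k0 * s(i) + k1`, the signal-proportional-plus-floor law.
#' The lightest demo regime is `k0 = 0.05, k1 = 4`.
#'
#' @param clean 3D array.
#' @param k0 proportional coefficient (>= 0).
#' @param k1 noise floor (>= 0); `k0` and `k1` must not both be zero.
#' @param seed integer RNG seed.
#' @return noisy volume.
#' @export
apply_nonstationary_gaussian <- function(clean, k0 = 0.05, k1 = 4,
                                         seed = 1L) {
  if (k0 < 0 || k1 < 0 || (k0 == 0 && k1 == 0))
    stop("need k0 >= 0, k1 >= 0, not both zero")
  set.seed(seed)
  clean + array(stats::rnorm(length(clean), sd = k0 * clean + k1),
                dim(clean))
}
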