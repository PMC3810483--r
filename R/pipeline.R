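.octd_cache <- new.env(parent = emptyenv())

#' In-plane orientation of each oriented subband
#'
#' Determines, once per session, the dominant in-plane stripe direction of
#' each of the 28 oriented subbands by synthesizing the subband's impulse
#' response, forming its analytic spectrum, and locating the peak
#' frequency: the wavelet's stripes run perpendicular to its centre
#' frequency.  Subbands whose spectral energy lies mostly along the
#' through-plane frequency axis have no meaningful planar direction and
#' get `NA` (the pipeline falls back to square windows for them).
#'
#' @return data frame with columns `orientation`, `f1`, `f2`, `f3`
#'   (signed centre frequency, cycles/voxel) and `theta` (stripe angle in
#'   degrees mod 180, or `NA`).
#' @export
subband_orientations <- function() {
  if (!is.null(.octd_cache$orient)) return(.octd_cache$orient)
  N <- 32L
  p0 <- forward_dtcwt3d(array(0, c(N, N, N)), 1L)
  ctr <- c(8L, 8L, 8L)
  out <- data.frame(orientation = 1:28, f1 = NA_real_, f2 = NA_real_,
                    f3 = NA_real_, theta = NA_real_)
  for (o in 1:28) {
    p <- p0
    p$subbands[[1]][[o]][ctr[1], ctr[2], ctr[3]] <- 1 + 0i
    ar <- inverse_dtcwt3d(p)
    p$subbands[[1]][[o]][ctr[1], ctr[2], ctr[3]] <- 0 + 1i
    ai <- inverse_dtcwt3d(p)
    E <- Mod(stats::fft(ar + 1i * ai))^2
    ix <- arrayInd(which.max(E), dim(E))
    f <- (ix - 1) / N
    f <- ifelse(f > 0.5, f - 1, f)
    out[o, c("f1", "f2", "f3")] <- f
    rho <- sqrt(f[1]^2 + f[2]^2)
    if (rho >= 0.5 * abs(f[3])) {
      # stripes are perpendicular to the in-plane frequency component
      out$theta[o] <- (atan2(f[1], -f[2]) * 180 / pi) %% 180
    }
  }
  .octd_cache$orient <- out
  out
}

#' Denoising run configuration
#'
#' Collects every tunable of the despeckling pipeline.  `windowing`
#' selects how local mixture parameters are estimated: `"square"` (fixed
#' local box — the plain local variant), `"lpa_ici"` (anisotropic
#' per-voxel windows — the shape-adaptive local variant), or `"global"`
#' (one window spanning the subband — the nonlocal variant).
#'
#' @param homomorphic log-transform intensities before the wavelet stage.
#' @param noise wavelet-domain noise law: `"gaussian"` or
#'   `"two_sided_rayleigh"`.
#' @param windowing `"square"`, `"lpa_ici"`, or `"global"`.
#' @param prior `"mixture"` (two-component bivariate Gaussian mixture) or
#'   `"single_gaussian"` (local-variance Wiener-type shrinkage).
#' @param levels transform scales (default 3).
#' @param em_iter EM sweeps per subband (default 5).
#' @param half_width square-window half-widths, see [window_spec()].
#' @param lpa_R,lpa_lengths,lpa_mode,lpa_order LPA-ICI settings, see
#'   [select_windows()].
#' @param epsilon homomorphic log offset (`NULL` = automatic rule).
#' @param complex_mode `"realimag"` shrinks real and imaginary parts as
#'   two independent coefficient fields (default); `"magnitude"` derives a
#'   gain from the coefficient moduli and applies it to the complex
#'   coefficient.
#' @return object of class `run_config`.
#' @export
run_config <- function(homomorphic = FALSE,
                       noise = c("gaussian", "two_sided_rayleigh"),
                       windowing = c("square", "lpa_ici", "global"),
                       prior = c("mixture", "single_gaussian"),
                       levels = 3L, em_iter = 5L,
                       half_width = c(3, 3, 1),
                       lpa_R = 2, lpa_lengths = c(1, 2, 3, 5, 8),
                       lpa_mode = "planar_L12_offset15", lpa_order = 0,
                       epsilon = NULL,
                       complex_mode = c("realimag", "magnitude")) {
  structure(list(homomorphic = isTRUE(homomorphic),
                 noise = match.arg(noise),
                 windowing = match.arg(windowing),
                 prior = match.arg(prior),
                 levels = as.integer(levels),
                 em_iter = as.integer(em_iter),
                 half_width = rep_len(as.integer(half_width), 3),
                 lpa_R = lpa_R, lpa_lengths = lpa_lengths,
                 lpa_mode = lpa_mode, lpa_order = lpa_order,
                 epsilon = epsilon,
                 complex_mode = match.arg(complex_mode)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key/value file mirroring the [run_config()] arguments; unknown keys
#' are rejected.  Used by the command-line interface.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# shrink one numeric coefficient field given its parent and fitted params
shrink_field <- function(y, yp, window, noise, config) {
  if (config$prior == "mixture") {
    params <- em_fit_impl(y, yp, window, config$em_iter, noise = noise)
    what <- if (noise$kind == "gaussian")
      bigauss_mix_shrink(y, yp, params, noise$sigma_n)
    else
      bigauss_ray_mix_shrink(y, yp, params, noise$alpha)
  } else {
    s2 <- pmax(win_sum(y^2 + yp^2, window) /
                 (2 * win_sum(array(1, dim(y)), window)) - noise$sigma_n^2,
               var_floor(y, yp))
    what <- if (noise$kind == "gaussian")
      y * s2 / (s2 + noise$sigma_n^2)
    else
      rayleigh_noise_gauss_prior(y, sqrt(s2), noise$alpha)
  }
  # MMSE estimates shrink; numerically enforce gain-boundedness
  sign(y) * pmin(abs(what), abs(y))
}

#' Despeckle a 3D OCT volume
#'
#' The full pipeline: (1) optional homomorphic log map; (2) forward 3D
#' dual-tree complex wavelet transform; (3) global noise level by the MAD
#' rule (`alpha = sigma_n / sqrt(2)` for the Rayleigh model); (4) for
#' LPA-ICI windowing, per-voxel directional window selection on the
#' low-pass residual, mapped to every subband scale; (5) per scale,
#' orientation, and complex part: pair with parent, fit the local mixture
#' (or local variance) over the chosen windows from the noisy data, apply
#' the matching MMSE shrinkage; (6) inverse transform; (7) optional
#' exponential map.  The low-pass residual passes through unmodified.
#'
#' @param volume numeric 3D array (nonnegative when `homomorphic`).
#' @param config a [run_config()].
#' @return list with `volume` (denoised array) and `diagnostics`
#'   (`sigma_n`, per-subband parameter summaries, window fallbacks,
#'   stage timings).
#' @export
denoise_volume <- function(volume, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  x <- volume
  if (config$homomorphic)
    x <- homomorphic_map(x, "forward", config$epsilon)
  epsilon <- attr(x, "epsilon")

  t0 <- proc.time()[3]
  pyr <- forward_dtcwt3d(x, config$levels)
  t_fwd <- proc.time()[3] - t0

  sigma_n <- estimate_noise_sigma(pyr)
  if (sigma_n <= 0) sigma_n <- 1e-12 * (1 + max(Mod(pyr$subbands[[1]][[1]])))
  noise <- noise_model(config$noise, sigma_n = sigma_n)

  wf <- NULL
  orient <- NULL
  fallbacks <- 0L
  if (config$windowing == "lpa_ici") {
    wf <- select_windows(pyr$lowpass, sigma_n,
                         direction_set(config$lpa_mode),
                         config$lpa_lengths, config$lpa_R,
                         config$lpa_order)
    orient <- subband_orientations()
  }

  t0 <- proc.time()[3]
  summaries <- list()
  for (j in seq_len(config$levels)) {
    for (o in 1:28) {
      pf <- pair_with_parent(pyr, j, o, self_pair_coarsest = TRUE)
      window <- switch(config$windowing,
        square = window_spec("square", config$half_width),
        global = window_spec("global"),
        lpa_ici = {
          sub <- windows_for_subband(wf, j, config$levels, dim(pf$child),
                                     orient$theta[o])
          if (is.null(sub)) {
            fallbacks <- fallbacks + 1L
            window_spec("square", config$half_width)
          } else window_spec("anisotropic", field = sub)
        })
      if (config$complex_mode == "realimag") {
        re <- shrink_field(Re(pf$child), Re(pf$parent), window, noise, config)
        im <- shrink_field(Im(pf$child), Im(pf$parent), window, noise, config)
        pyr$subbands[[j]][[o]] <- re + 1i * im
      } else {
        m <- Mod(pf$child)
        gh <- shrink_field(m, Mod(pf$parent), window, noise, config)
        gain <- ifelse(m > 0, gh / m, 0)
        pyr$subbands[[j]][[o]] <- pf$child * gain
      }
      if (o %in% c(1, 15)) {
        summaries[[length(summaries) + 1]] <-
          data.frame(scale = j, orientation = o,
                     energy_in = sum(Mod(pf$child)^2),
                     energy_out = sum(Mod(pyr$subbands[[j]][[o]])^2))
      }
    }
  }
  t_shrink <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  out <- inverse_dtcwt3d(pyr)
  t_inv <- proc.time()[3] - t0
  if (config$homomorphic)
    out <- homomorphic_map(out, "inverse", epsilon)
  out <- array(as.numeric(out), dim(volume))
  if (!all(is.finite(out)))
    stop("non-finite values after inversion stage")
  list(volume = out,
       diagnostics = list(
         sigma_n = sigma_n,
         window_fallbacks = fallbacks,
         subband_summary = do.call(rbind, summaries),
         timings = c(forward = t_fwd, shrink = t_shrink, inverse = t_inv,
                     total = proc.time()[3] - t_all)))
}
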