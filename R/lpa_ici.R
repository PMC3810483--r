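# ---- direction sets --------------------------------------------------------

#' Directional bases for anisotropic window selection
#'
#' Direction sets for the LPA-ICI procedure.  Planar sets live in the
#' B-scan plane (axes 1-2): `"planar_L8"` uses 8 directions at 45 degree
#' spacing starting from 0; `"planar_L12_offset15"` uses 12 directions at
#' 30 degree spacing offset by 15 degrees, which is the fast variant whose
#' six opposite pairs line up with the in-plane orientations of the
#' complex subbands.  Both include the two through-plane axes (+-axis 3).
#' `"cones_3d"` uses the 26 unit-neighbour directions with a 30 degree
#' half-angle cone of voxels around each axis.
#'
#' Each direction is realized on the voxel grid as a nested family of
#' integer offsets: a ray `round(t * u)` for planar/axial directions, or
#' all voxels of norm at most `t` inside the cone.  Offsets are tagged
#' with the step at which they enter, so windowed sums can be grown
#' incrementally.
#'
#' @param mode one of `"planar_L8"`, `"planar_L12_offset15"`, `"cones_3d"`.
#' @param max_len largest segment length that will ever be requested.
#' @return object of class `direction_set`: list with `mode`, `angles`
#'   (planar angles in degrees, `NA` for axial/cone axes), and `offsets`
#'   (per direction, an integer matrix with columns enter-step, dx, dy, dz).
#' @export
direction_set <- function(mode = c("planar_L12_offset15", "planar_L8",
                                   "cones_3d"), max_len = 64) {
  mode <- match.arg(mode)
  ray <- function(u) dir_ray(u, max_len)
  if (mode %in% c("planar_L8", "planar_L12_offset15")) {
    angles <- if (mode == "planar_L8") seq(0, 315, by = 45)
              else seq(15, 345, by = 30)
    offs <- lapply(angles, function(th)
      ray(c(cospi(th / 180), sinpi(th / 180), 0)))
    angles <- c(angles, NA, NA)
    offs <- c(offs, list(ray(c(0, 0, 1)), ray(c(0, 0, -1))))
  } else {
    axes <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    axes <- axes[rowSums(abs(axes)) > 0, ]
    angles <- rep(NA_real_, nrow(axes))
    offs <- lapply(seq_len(nrow(axes)), function(i) {
      u <- axes[i, ] / sqrt(sum(axes[i, ]^2))
      r <- max_len
      cand <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
      nrm <- sqrt(rowSums(cand^2))
      proj <- as.vector(cand %*% u)
      keep <- (nrm == 0) | (proj > 0 & proj / pmax(nrm, 1e-12) >= cospi(30 / 180) &
                              nrm <= r)
      cand <- cand[keep, , drop = FALSE]
      nrm <- nrm[keep]
      enter <- pmax(1, ceiling(nrm))
      ord <- order(enter)
      cbind(enter[ord], cand[ord, , drop = FALSE])
    })
  }
  structure(list(mode = mode, angles = angles, offsets = offs),
            class = "direction_set")
}

# discrete one-sided ray along unit direction u: distinct voxel offsets
# round(t * u), tagged with the step (= number of distinct voxels so far)
dir_ray <- function(u, max_len) {
  off <- unique(t(vapply(seq_len(max_len) - 1,
                         function(t) round(t * u), numeric(3))))
  cbind(seq_len(nrow(off)), off)
}

#' Directional local polynomial approximation kernels
#'
#' For each direction and each window length `h`, a finite-support weight
#' kernel on the one-sided directional segment (or cone) of extent `h`.
#' Order 0 kernels are uniform (weights sum to 1); order 1 kernels are the
#' minimum-norm weights reproducing linear trends along the direction
#' (weights sum to 1, first moment along the direction vanishes), which
#' makes them exact on linear ramps.  Segments too short to support the
#' requested order fall back to order 0.
#'
#' @param directions a [direction_set()].
#' @param lengths strictly increasing integer window lengths.
#' @param poly_order 0 (box) or 1 (linear).
#' @return list over directions of lists over lengths; each kernel is a
#'   list with integer `offsets` (rows dx, dy, dz) and numeric `weights`.
#' @export
build_directional_kernels <- function(directions, lengths, poly_order = 0) {
  stopifnot(inherits(directions, "direction_set"))
  if (any(diff(lengths) <= 0)) stop("`lengths` must be strictly increasing")
  if (!poly_order %in% c(0, 1)) stop("poly_order must be 0 or 1")
  lapply(directions$offsets, function(offs) {
    lapply(lengths, function(h) {
      sel <- offs[offs[, 1] <= h, , drop = FALSE]
      o <- sel[, 2:4, drop = FALSE]
      n <- nrow(o)
      if (poly_order == 0 || n < 2) {
        w <- rep(1 / n, n)
      } else {
        t <- sqrt(rowSums(o^2))         # signed position along the ray
        A <- rbind(c(n, sum(t)), c(sum(t), sum(t^2)))
        lam <- solve(A, c(1, 0))
        w <- lam[1] + lam[2] * t
      }
      list(offsets = o, weights = w)
    })
  })
}

# ---- ICI rule --------------------------------------------------------------

#' Intersection-of-confidence-intervals scale selection
#'
#' Given a sequence of directional estimates with growing support and their
#' standard deviations, forms the confidence intervals
#' `C_s = [est_s - R sd_s, est_s + R sd_s]` and returns the largest index
#' `s+` such that the running intersection `D_s = C_1 n ... n C_s` is
#' nonempty.  Vectorized over voxels: `estimates` and `stds` may be
#' matrices (voxels x scales).
#'
#' @param estimates numeric vector (one voxel) or matrix of estimates.
#' @param stds positive standard deviations, recycled across voxels if a
#'   vector.
#' @param R smoothing parameter scaling the interval half-widths.
#' @return integer vector of selected indices `s+` (>= 1).
#' @export
ici_select <- function(estimates, stds, R) {
  if (is.null(dim(estimates)))
    estimates <- matrix(estimates, nrow = 1)
  if (is.null(dim(stds)))
    stds <- matrix(stds, nrow = nrow(estimates), ncol = ncol(estimates),
                   byrow = TRUE)
  if (ncol(estimates) == 0) stop("empty estimate sequence")
  J <- ncol(estimates)
  lower <- estimates[, 1] - R * stds[, 1]
  upper <- estimates[, 1] + R * stds[, 1]
  splus <- rep.int(1L, nrow(estimates))
  alive <- rep.int(TRUE, nrow(estimates))
  for (s in seq_len(J - 1) + 1) {
    lower <- pmax(lower, estimates[, s] - R * stds[, s])
    upper <- pmin(upper, estimates[, s] + R * stds[, s])
    alive <- alive & (lower <= upper)
    splus[alive] <- s
  }
  splus
}

# ---- per-voxel window selection --------------------------------------------

# apply one kernel to a field with boundary renormalization; returns the
# estimate and the per-voxel sum of squared (renormalized) weights
apply_kernel <- function(field, kern, ones) {
  num <- 0; den <- 0; w2 <- 0
  for (r in seq_len(nrow(kern$offsets))) {
    s <- shift3(field, kern$offsets[r, ])
    ind <- shift3(ones, kern$offsets[r, ])
    num <- num + kern$weights[r] * s
    den <- den + kern$weights[r] * ind
    w2 <- w2 + kern$weights[r]^2 * ind
  }
  den <- ifelse(abs(den) < 1e-6, 1, den)
  list(est = num / den, sumw2 = w2 / den^2)
}

#' Per-voxel anisotropic window selection by LPA-ICI
#'
#' Convolves the field with the directional kernel bank and applies the
#' ICI rule per voxel and direction, yielding the adaptive directional
#' extents `h+(k, theta)`.  The anisotropic window at `k` is the star-shaped
#' union of the selected directional segments.  Interval standard
#' deviations use the white-noise rule `sd_s^2 = sigma^2 * sum(g^2)` for
#' each kernel `g`.
#'
#' @param field 3D numeric array (typically a low-pass subband).
#' @param sigma noise standard deviation on `field`.
#' @param directions a [direction_set()].
#' @param lengths increasing candidate segment lengths
#'   (default `c(1, 2, 3, 5, 8)`).
#' @param R ICI smoothing parameter (default 2).
#' @param poly_order LPA order passed to [build_directional_kernels()].
#' @return object of class `window_field`: list with `offsets` (per kept
#'   direction), `hplus` (array voxels x directions of selected lengths),
#'   `angles`, `lengths`, `R`.
#' @export
select_windows <- function(field, sigma, directions = direction_set(),
                           lengths = c(1, 2, 3, 5, 8), R = 2,
                           poly_order = 0) {
  stopifnot(all(is.finite(field)))
  kerns <- build_directional_kernels(directions, lengths, poly_order)
  d <- dim(field)
  ones <- array(1, d)
  nd <- length(kerns)
  hplus <- array(0L, c(d, nd))
  for (di in seq_len(nd)) {
    ests <- matrix(0, prod(d), length(lengths))
    stds <- matrix(0, prod(d), length(lengths))
    for (si in seq_along(lengths)) {
      ak <- apply_kernel(field, kerns[[di]][[si]], ones)
      ests[, si] <- as.vector(ak$est)
      stds[, si] <- sigma * sqrt(as.vector(ak$sumw2))
    }
    sp <- ici_select(ests, stds, R)
    hplus[, , , di] <- array(lengths[sp], d)
  }
  structure(list(offsets = directions$offsets, hplus = hplus,
                 angles = directions$angles, lengths = lengths, R = R),
            class = "window_field")
}

#' Map low-pass window lengths to an oriented subband
#'
#' The fast LPA-ICI variant runs window selection only on the low-pass
#' residual; an oriented subband at scale `j` then reuses the selected
#' lengths at the corresponding (coarser-grid) location, scaled by
#' `2^(j-1)`, along the direction pair matching the subband's in-plane
#' orientation, together with the two through-plane axes.  Subbands with
#' no in-plane orientation (energy concentrated along the depth-frequency
#' axis) have no matching planar pair and return `NULL`, signalling the
#' caller to fall back to a square window.
#'
#' @param lowpass_field a `window_field` computed on the scale-`levels`
#'   low-pass grid.
#' @param scale subband scale `j` (1 = finest).
#' @param levels total number of pyramid scales.
#' @param target_dims dimension vector of the subband grid at scale `j`.
#' @param theta matched in-plane stripe angle of the subband in degrees
#'   (mod 180), or `NA` for no planar match.
#' @return a `window_field` on the subband grid, or `NULL` when no
#'   direction pair matches.
#' @export
windows_for_subband <- function(lowpass_field, scale, levels, target_dims,
                                theta) {
  stopifnot(inherits(lowpass_field, "window_field"))
  ang <- lowpass_field$angles
  planar <- which(!is.na(ang))
  axial <- which(is.na(ang))
  if (is.na(theta)) return(NULL)
  # the two opposite planar directions closest to theta (mod 180)
  dd <- abs(((ang[planar] - theta) + 90) %% 180 - 90)
  keep_pl <- planar[order(dd)[1:2]]
  keep <- c(keep_pl, axial)
  fac <- 2^(levels - scale)
  scl <- 2^(scale - 1)
  hp <- lowpass_field$hplus
  d0 <- dim(hp)[1:3]
  idx <- lapply(1:3, function(ax)
    pmin(ceiling(seq_len(target_dims[ax]) / fac), d0[ax]))
  sub <- array(0L, c(target_dims, length(keep)))
  for (i in seq_along(keep)) {
    h <- hp[, , , keep[i], drop = FALSE][idx[[1]], idx[[2]], idx[[3]], 1,
                                         drop = FALSE]
    sub[, , , i] <- scl * h
  }
  # regenerate offset rays long enough for the scaled lengths
  maxlen <- max(sub) + 1
  offs <- c(lapply(ang[keep_pl], function(th)
    dir_ray(c(cospi(th / 180), sinpi(th / 180), 0), maxlen)),
    list(dir_ray(c(0, 0, 1), maxlen), dir_ray(c(0, 0, -1), maxlen)))
  structure(list(offsets = offs, hplus = sub,
                 angles = c(ang[keep_pl], NA, NA),
                 lengths = scl * lowpass_field$lengths,
                 R = lowpass_field$R),
            class = "window_field")
}
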