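# ---- windowed sums ---------------------------------------------------------

#' Estimation window specification
#'
#' Describes the neighbourhood over which local mixture parameters are
#' estimated: a centred axis-aligned box (`"square"`, truncated at grid
#' boundaries), the whole subband (`"global"`, the nonlocal variant), or a
#' per-voxel star of directional segments selected by LPA-ICI
#' (`"anisotropic"`, see [select_windows()] / [windows_for_subband()]).
#'
#' @param mode window mode.
#' @param half_width integer half-widths per axis for `"square"` (recycled
#'   to length 3).  The default `c(3, 3, 1)` gives a 7 x 7 x 3 box: OCT
#'   voxels are anisotropic, so the through-plane extent is kept small.
#' @param field a `window_field` for `"anisotropic"` mode.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(mode = c("square", "global", "anisotropic"),
                        half_width = c(3, 3, 1), field = NULL) {
  mode <- match.arg(mode)
  half_width <- rep_len(as.integer(half_width), 3)
  if (mode == "square" && any(half_width < 0))
    stop("half_width must be >= 0")
  if (mode == "anisotropic" && !inherits(field, "window_field"))
    stop("anisotropic mode requires a `window_field`")
  structure(list(mode = mode, half_width = half_width, field = field),
            class = "window_spec")
}

# g[k] = f[k + s] with zeros outside the grid
shift3 <- function(f, s) {
  d <- dim(f)
  g <- array(0, d)
  src <- lapply(1:3, function(ax) seq_len(d[ax]) + s[ax])
  ok <- lapply(1:3, function(ax) src[[ax]] >= 1 & src[[ax]] <= d[ax])
  if (!all(vapply(ok, any, logical(1)))) return(g)
  ti <- lapply(1:3, function(ax) seq_len(d[ax])[ok[[ax]]])
  si <- lapply(1:3, function(ax) src[[ax]][ok[[ax]]])
  g[ti[[1]], ti[[2]], ti[[3]]] <- f[si[[1]], si[[2]], si[[3]]]
  g
}

# centred box sum along one axis, truncated at the boundary
boxsum_dim <- function(a, ax, hw) {
  if (hw == 0) return(a)
  perm <- c(ax, setdiff(1:3, ax))
  inv <- order(perm)
  ap <- aperm(a, perm)
  dp <- dim(ap)
  X <- matrix(ap, nrow = dp[1])
  n <- dp[1]
  cs <- X
  for (i in seq_len(n - 1) + 1) cs[i, ] <- cs[i - 1, ] + X[i, ]
  hi <- pmin(seq_len(n) + hw, n)
  lo <- seq_len(n) - hw - 1
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 1
  out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  aperm(array(out, dp), inv)
}

boxsum3 <- function(a, hw) {
  for (ax in 1:3) a <- boxsum_dim(a, ax, hw[ax])
  a
}

# sum of f over the star window at every voxel: union of the directional
# segments of per-voxel length stored in the window field.  Each direction's
# offset list is nested in the step index, so partial sums are built
# incrementally and selected per voxel by its chosen length.
star_sum <- function(f, field) {
  nd <- length(field$offsets)
  tot <- 0
  for (di in seq_len(nd)) {
    offs <- field$offsets[[di]]        # matrix: enter-step, dx, dy, dz
    lens <- field$hplus[, , , di]
    uq <- sort(unique(as.vector(lens)))
    P <- 0
    done <- 0
    sel <- array(0, dim(f))
    for (L in uq) {
      take <- which(offs[, 1] > done & offs[, 1] <= L)
      for (r in take) P <- P + shift3(f, offs[r, 2:4])
      done <- L
      m <- lens == L
      sel[m] <- P[m]
    }
    tot <- tot + sel
  }
  tot - (nd - 1) * f   # every direction contains the centre voxel once
}

# windowed sum of `f` under a window_spec (f an array; returns array)
win_sum <- function(f, window) {
  switch(window$mode,
         square = boxsum3(f, window$half_width),
         global = array(sum(f), dim(f)),
         anisotropic = star_sum(f, window$field))
}

# ---- local variance and EM -------------------------------------------------

var_floor <- function(y, yp) {
  max(1e-12 * mean(y^2 + yp^2) / 2, 1e-300)
}

#' Windowed empirical variance of a coefficient pair field
#'
#' The single-Gaussian local prior scale:
#' `sigma^2(k) = (1/2M) sum_{j in N(k)} (y(j)^2 + yp(j)^2) - sigma_n^2`,
#' clipped from below at a small positive floor.  Used by the Wiener and
#' single-component Rayleigh shrinkage variants and as the EM initializer.
#'
#' @param pairs a `pair_field` (complex parts allowed; see `part`) or a
#'   list with numeric arrays `child`, `parent`.
#' @param window a [window_spec()].
#' @param sigma_n noise standard deviation subtracted from the raw moment.
#' @param part for complex pair fields, which part to use
#'   (`"re"` or `"im"`).
#' @return array of variance estimates, same shape as the child grid.
#' @export
local_variance_estimate <- function(pairs, window, sigma_n = 0,
                                    part = c("re", "im")) {
  pp <- pair_parts(pairs, match.arg(part))
  M <- win_sum(array(1, dim(pp$y)), window)
  s2 <- win_sum(pp$y^2 + pp$yp^2, window) / (2 * M) - sigma_n^2
  pmax(s2, var_floor(pp$y, pp$yp))
}

pair_parts <- function(pairs, part = "re") {
  y <- pairs$child
  yp <- pairs$parent
  if (is.complex(y)) {
    if (part == "re") {
      y <- Re(y); yp <- Re(yp)
    } else {
      y <- Im(y); yp <- Im(yp)
    }
  }
  if (is.null(dim(y))) {
    y <- array(y, c(length(y), 1, 1))
    yp <- array(yp, c(length(yp), 1, 1))
  }
  list(y = y, yp = yp)
}

# Shared EM driver.  For noisy data the E-step responsibilities use the
# component evidence densities (prior convolved with the noise) and the
# M-step subtracts the noise variance from the windowed second moments;
# with sigma_n = 0 both reduce to the clean-data algorithm.
em_fit_impl <- function(y, yp, window, n_iter, noise = NULL) {
  flo <- var_floor(y, yp)
  sn2 <- if (is.null(noise)) 0 else noise$sigma_n^2
  ones <- array(1, dim(y))
  M <- win_sum(ones, window)
  s2hat <- pmax(win_sum(y^2 + yp^2, window) / (2 * M) - sn2, flo)
  a <- array(0.5, dim(y))
  s11 <- sqrt(2 * s2hat); s12 <- s11
  s21 <- sqrt(0.5 * s2hat); s22 <- s21
  Sy2 <- win_sum(y^2, window)
  Syp2 <- win_sum(yp^2, window)
  loglik <- numeric(0)
  for (it in seq_len(n_iter)) {
    if (is.null(noise)) {
      l1 <- -y^2 / (2 * s11^2) - yp^2 / (2 * s12^2) - log(s11 * s12)
      l2 <- -y^2 / (2 * s21^2) - yp^2 / (2 * s22^2) - log(s21 * s22)
    } else if (noise$kind == "gaussian") {
      l1 <- evidence_gaussian(y, yp, s11, s12, noise$sigma_n, log = TRUE)
      l2 <- evidence_gaussian(y, yp, s21, s22, noise$sigma_n, log = TRUE)
    } else {
      l1 <- evidence_rayleigh(y, yp, s11, s12, noise$alpha, log = TRUE)
      l2 <- evidence_rayleigh(y, yp, s21, s22, noise$alpha, log = TRUE)
    }
    la <- log(a); l1a <- log1p(-a)
    if (window$mode == "global")
      loglik <- c(loglik, sum(log(exp(l1 - pmax(l1, l2)) * a +
                                  exp(l2 - pmax(l1, l2)) * (1 - a)) +
                              pmax(l1, l2)))
    r1 <- stats::plogis((la + l1) - (l1a + l2))
    S1 <- win_sum(r1, window)
    S1 <- pmin(pmax(S1, 1e-12), M - 1e-12)
    a <- S1 / M
    S1y2 <- win_sum(r1 * y^2, window)
    S1yp2 <- win_sum(r1 * yp^2, window)
    s11 <- sqrt(pmax(S1y2 / S1 - sn2, flo))
    s12 <- sqrt(pmax(S1yp2 / S1 - sn2, flo))
    s21 <- sqrt(pmax((Sy2 - S1y2) / (M - S1) - sn2, flo))
    s22 <- sqrt(pmax((Syp2 - S1yp2) / (M - S1) - sn2, flo))
  }
  # all-zero windows carry no information: keep the initial mixing weight
  dead <- (Sy2 + Syp2) <= 0
  if (any(dead)) a[dead] <- 0.5
  # identifiability: component 1 is the larger-child-scale component
  swap <- s21 > s11
  if (any(swap)) {
    tmp <- s11[swap]; s11[swap] <- s21[swap]; s21[swap] <- tmp
    tmp <- s12[swap]; s12[swap] <- s22[swap]; s22[swap] <- tmp
    a[swap] <- 1 - a[swap]
  }
  out <- mixture_params(a, s11, s12, s21, s22, floor_sd = sqrt(flo))
  attr(out, "loglik") <- loglik
  out
}

#' Local EM fit of the mixture prior from clean coefficient pairs
#'
#' Windowed expectation-maximization for the five per-coefficient mixture
#' parameters: the E-step computes component responsibilities from the
#' current local parameters; the M-step re-estimates the mixing weight as
#' the windowed mean responsibility and the component variances as
#' responsibility-weighted windowed second moments of the child and parent
#' coefficients.  Initialization is deterministic (`a = 0.5`, component
#' variances at twice and half the windowed empirical variance).
#'
#' @inheritParams local_variance_estimate
#' @param n_iter number of EM sweeps (default 5; parameters are per voxel,
#'   so a fixed small number is used rather than a convergence test).
#' @return a [mixture_params()] object with array fields; for global
#'   windows the attribute `"loglik"` traces the total data log-likelihood
#'   before each sweep.
#' @export
em_fit_clean <- function(pairs, window, n_iter = 5, part = c("re", "im")) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  pp <- pair_parts(pairs, match.arg(part))
  em_fit_impl(pp$y, pp$yp, window, n_iter, noise = NULL)
}

#' Local EM fit of the mixture prior from noisy coefficient pairs
#'
#' As [em_fit_clean()], but the observed pairs carry additive noise: the
#' E-step responsibilities use the component evidence densities under the
#' given noise model and the M-step subtracts the noise variance
#' `sigma_n^2` from every windowed second moment, clipping at the variance
#' floor so degenerate windows cannot produce negative variances.
#'
#' @inheritParams em_fit_clean
#' @param noise a [noise_model()] with known `sigma_n` (from
#'   [estimate_noise_sigma()]).
#' @return a [mixture_params()] object with array fields.
#' @export
em_fit_noisy <- function(pairs, noise, window, n_iter = 5,
                         part = c("re", "im")) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$sigma_n <= 0) stop("noise sigma_n must be positive")
  if (n_iter < 1) stop("n_iter must be >= 1")
  pp <- pair_parts(pairs, match.arg(part))
  em_fit_impl(pp$y, pp$yp, window, n_iter, noise = noise)
}
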