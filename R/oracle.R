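# Panel-composite Gauss-Legendre quadrature over a rectangle with uniform
# refinement until two successive panelizations agree to reltol.  Preferred
# over generic adaptive cubature here because the integrands (posterior
# numerators/denominators) have huge dynamic range and near-degenerate
# ridges that defeat error estimators based on local ratios.
gl2d_quad <- function(f, xa, xb, ya, yb, reltol = 1e-9, max_halvings = 6) {
  gl <- pracma::gaussLegendre(10, 0, 1)
  panel_nodes <- function(a, b, k) {
    # k panels on [a, b]; returns nodes and weights
    brk <- seq(a, b, length.out = k + 1)
    w <- rep(gl$w * (brk[2] - brk[1]), k)
    x <- as.vector(outer(gl$x * (brk[2] - brk[1]), brk[-(k + 1)], `+`))
    list(x = x, w = w)
  }
  val <- function(k) {
    px <- panel_nodes(xa, xb, k)
    py <- panel_nodes(ya, yb, k)
    Fm <- f(outer(px$x, rep(1, length(py$x))),
            outer(rep(1, length(px$x)), py$x))
    as.numeric(px$w %*% Fm %*% py$w)
  }
  k <- 4
  old <- val(k)
  for (i in seq_len(max_halvings)) {
    k <- 2 * k
    new <- val(k)
    if (abs(new - old) <= reltol * max(abs(new), 1e-300)) return(new)
    old <- new
  }
  old
}

#' Numerical MMSE posterior-mean oracle
#'
#' Ground-truth engine for the closed-form shrinkage functions: evaluates
#' the posterior mean
#' \deqn{\hat w = \frac{\iint w_1\, p_n(y - w_1, y_p - w_2)\, p_w(w_1, w_2)\,
#'   dw_1 dw_2}{\iint p_n(y - w_1, y_p - w_2)\, p_w(w_1, w_2)\, dw_1 dw_2}}
#' by refined composite Gauss-Legendre quadrature over a box of half-width
#' `half_width`.  The integration domain is split along `w1 = y` and
#' `w2 = yp`, where densities with an absolute-value factor (two-sided
#' Rayleigh noise) have kinks, and both integrands are rescaled by the
#' maximum of the joint density on a coarse grid so extreme parameter
#' values cannot underflow.
#'
#' @param y,yp scalar noisy child and parent coefficients.
#' @param prior_pdf function `(w1, w2) -> density` (vectorized).
#' @param noise_pdf function `(n1, n2) -> density` (vectorized).
#' @param half_width integration box half-width; should cover at least
#'   8 standard deviations of both densities.
#' @param reltol relative tolerance of the panel refinement.
#' @return scalar posterior-mean estimate.
#' @export
mmse_quadrature_oracle <- function(y, yp, prior_pdf, noise_pdf,
                                   half_width, reltol = 1e-9) {
  stopifnot(length(y) == 1L, length(yp) == 1L, half_width > 0)
  joint <- function(w1, w2) noise_pdf(y - w1, yp - w2) * prior_pdf(w1, w2)
  g <- seq(-half_width, half_width, length.out = 61)
  sc <- max(joint(outer(g, rep(1, 61)), outer(rep(1, 61), g)),
            joint(y, yp), joint(0, 0), na.rm = TRUE)
  if (!is.finite(sc) || sc <= 0) sc <- 1
  xs <- sort(unique(c(-half_width, half_width, if (abs(y) < half_width) y)))
  ys <- sort(unique(c(-half_width, half_width, if (abs(yp) < half_width) yp)))
  tile_sum <- function(f) {
    tot <- 0
    for (i in seq_len(length(xs) - 1)) {
      for (j in seq_len(length(ys) - 1)) {
        tot <- tot + gl2d_quad(f, xs[i], xs[i + 1], ys[j], ys[j + 1],
                               reltol = reltol)
      }
    }
    tot
  }
  num <- tile_sum(function(w1, w2) w1 * joint(w1, w2) / sc)
  den <- tile_sum(function(w1, w2) joint(w1, w2) / sc)
  num / den
}
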