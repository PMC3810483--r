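#' Local bivariate Gaussian mixture prior parameters
#'
#' Container for the per-coefficient parameters of the two-component
#' zero-mean bivariate Gaussian mixture prior on parent-child wavelet
#' coefficient pairs: mixing weight `a` and component standard deviations
#' `s11`, `s12` (component 1: child, parent) and `s21`, `s22`
#' (component 2).  Fields may be scalars or arrays of a common shape and
#' are recycled; standard deviations are clipped from below at
#' `floor_sd` so densities stay finite on degenerate windows.
#'
#' @param a mixing weight(s) in `[0, 1]`.
#' @param s11,s12,s21,s22 nonnegative component standard deviations.
#' @param floor_sd lower clip for the standard deviations.
#' @return object of class `mixture_params` (a list of the five fields).
#' @export
mixture_params <- function(a, s11, s12, s21, s22, floor_sd = 1e-9) {
  if (any(a < 0 | a > 1)) stop("`a` must lie in [0, 1]")
  if (any(c(s11, s12, s21, s22) < 0)) stop("standard deviations must be >= 0")
  structure(list(a = a,
                 s11 = pmax(s11, floor_sd), s12 = pmax(s12, floor_sd),
                 s21 = pmax(s21, floor_sd), s22 = pmax(s22, floor_sd)),
            class = "mixture_params")
}

#' Bivariate mixture prior density
#'
#' Density of the parent-child pair `(w1, w2)` under the local mixture
#' prior: `a N(w1; s11) N(w2; s12) + (1 - a) N(w1; s21) N(w2; s22)`, each
#' factor a zero-mean univariate Gaussian.  Although the two coordinates
#' are uncorrelated under this prior, they are not independent unless
#' `a` is 0 or 1 — which is exactly how it encodes the parent-child
#' magnitude dependency.
#'
#' @param w1,w2 evaluation points (vectorized).
#' @param params a [mixture_params()] object.
#' @return density values.
#' @export
mixture_pdf2 <- function(w1, w2, params) {
  params$a * stats::dnorm(w1, 0, params$s11) * stats::dnorm(w2, 0, params$s12) +
    (1 - params$a) * stats::dnorm(w1, 0, params$s21) *
      stats::dnorm(w2, 0, params$s22)
}

#' Marginal mixture prior density
#'
#' Child-coordinate marginal of [mixture_pdf2()]: a univariate two-component
#' zero-mean Gaussian mixture, `a N(w1; s11) + (1 - a) N(w1; s21)` — the
#' classical leptokurtic ("peaky with heavy tails") model for wavelet
#' coefficient histograms.
#'
#' @inheritParams mixture_pdf2
#' @return density values.
#' @export
marginal_pdf1 <- function(w1, params) {
  params$a * stats::dnorm(w1, 0, params$s11) +
    (1 - params$a) * stats::dnorm(w1, 0, params$s21)
}

#' Excess-kurtosis check of the marginal prior
#'
#' Closed-form kurtosis of the marginal mixture: exceeds 3 (the Gaussian
#' value) whenever the two component scales differ and `0 < a < 1`.
#'
#' @param params a [mixture_params()] object with scalar fields.
#' @return scalar kurtosis of the child marginal.
#' @export
marginal_kurtosis <- function(params) {
  m2 <- params$a * params$s11^2 + (1 - params$a) * params$s21^2
  m4 <- 3 * (params$a * params$s11^4 + (1 - params$a) * params$s21^4)
  m4 / m2^2
}

#' Sample parent-child pairs from the mixture prior
#'
#' Draws `n` pairs by Bernoulli component selection followed by independent
#' zero-mean Gaussian draws with the selected component's child and parent
#' scales.  Used by the EM recovery tests; reproducible given `seed`.
#'
#' @param params a [mixture_params()] object with scalar fields.
#' @param n number of pairs (>= 1).
#' @param seed integer RNG seed.
#' @return list with numeric vectors `w1`, `w2` and integer `component`.
#' @export
sample_pairs <- function(params, n, seed) {
  if (n < 1) stop("`n` must be >= 1")
  stopifnot(length(params$a) == 1L)
  set.seed(seed)
  comp <- ifelse(stats::runif(n) < params$a, 1L, 2L)
  w1 <- stats::rnorm(n, 0, ifelse(comp == 1L, params$s11, params$s21))
  w2 <- stats::rnorm(n, 0, ifelse(comp == 1L, params$s12, params$s22))
  list(w1 = w1, w2 = w2, component = comp)
}
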