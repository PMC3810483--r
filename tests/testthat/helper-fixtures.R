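# Shared fixtures, built in code and memoised per test run.

.fix <- new.env()

# small layered phantom (fast pipeline tests)
small_phantom <- function() {
  if (is.null(.fix$small)) {
    spec <- phantom_spec(shape = c(64L, 64L, 16L),
                         layers = rbind(c(18, 30), c(8, 180), c(10, 120),
                                        c(8, 200), c(10, 90), c(10, 55)),
                         lesion = list(center = c(36, 32, 8),
                                       semi_axes = c(6, 10, 5),
                                       intensity = 40),
                         seed = 1L)
    .fix$small <- make_layered_phantom(spec)
  }
  .fix$small
}

# the full-size study phantom of the end-to-end checks
study_phantom <- function() {
  if (is.null(.fix$study)) .fix$study <- make_layered_phantom()
  .fix$study
}

# tensor-product Gauss-Legendre integral of f(x, y) over a rectangle
gl_grid_integral <- function(f, xa, xb, ya, yb, n = 240) {
  gx <- pracma::gaussLegendre(n, xa, xb)
  gy <- pracma::gaussLegendre(n, ya, yb)
  Fm <- f(outer(gx$x, rep(1, n)), outer(rep(1, n), gy$x))
  as.numeric(gx$w %*% Fm %*% gy$w)
}

# relative difference with an absolute guard near zero
rel_err <- function(value, truth, guard = 1e-9) {
  abs(value - truth) / pmax(abs(truth), guard)
}

# seeded white-noise volume
noise_volume <- function(dims, sigma, seed) {
  set.seed(seed)
  array(stats::rnorm(prod(dims), sd = sigma), dims)
}
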