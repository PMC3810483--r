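gauss_noise_pdf <- function(sigma_n) {
  m <- noise_model("gaussian", sigma_n = sigma_n)
  function(n1, n2) noise_pdf_bivariate(n1, n2, m)
}
ray_noise_pdf <- function(alpha) {
  m <- noise_model("two_sided_rayleigh", alpha = alpha)
  function(n1, n2) noise_pdf_bivariate(n1, n2, m)
}

test_that("erfcx_scaled matches its integral definition and asymptotics", {
  expect_equal(erfcx_scaled(0), 1)
  expect_lt(abs(100 * sqrt(pi) * erfcx_scaled(100) - 1), 1e-4)
  iq <- pracma::integral(function(t) 2 / sqrt(pi) * exp(-t^2 - 2 * t * 0.5),
                         0, 60, reltol = 1e-13)
  expect_lt(abs(erfcx_scaled(0.5) - iq), 1e-10)
  # branch seam and extreme arguments stay smooth/finite
  expect_lt(abs(erfcx_scaled(1.9999999) - erfcx_scaled(2.0000001)), 1e-6)
  expect_true(is.finite(erfcx_scaled(1e4)))
  expect_equal(erfcx_scaled(-1), 2 * exp(1) - erfcx_scaled(1))
})

test_that("Wiener shrinkage: gains, degenerate noise, oracle agreement", {
  expect_equal(wiener_bivariate(3, -2, 1.5, 2, 0)$child, 3)
  expect_equal(wiener_bivariate(2, 2, 1, 1, 1)$child, 1)
  expect_error(wiener_bivariate(1, 1, 0, 1, 0), "zero")
  o <- mmse_quadrature_oracle(2, 1,
                              function(a, b) dnorm(a, 0, 1.5) * dnorm(b, 0, 1.5),
                              gauss_noise_pdf(1), 15)
  expect_lt(rel_err(wiener_bivariate(2, 1, 1.5, 1.5, 1)$child, o), 1e-6)
})

test_that("Rayleigh-noise Gaussian-prior estimator is the posterior mean", {
  expect_equal(rayleigh_noise_gauss_prior(0, 2, 1), 0)
  ys <- c(0.3, 1, 2.7, 6)
  expect_equal(rayleigh_noise_gauss_prior(-ys, 2, 1),
               -rayleigh_noise_gauss_prior(ys, 2, 1))
  pr <- function(a, b) dnorm(a, 0, 2) * dnorm(b, 0, 2)
  for (y in c(0.5, 1, 2, 5)) {
    o <- mmse_quadrature_oracle(y, 1, pr, ray_noise_pdf(1), 20)
    expect_lt(rel_err(rayleigh_noise_gauss_prior(y, 2, 1), o), 1e-4)
  }
  expect_error(rayleigh_noise_gauss_prior(1, -1, 1), "positive")
  # the printed alternates are evaluable but are not the posterior mean
  expect_true(is.finite(rayleigh_noise_gauss_prior(2, 2, 1, "printed_a")))
  expect_true(is.finite(rayleigh_noise_gauss_prior(2, 2, 1, "printed_b")))
})

test_that("evidence densities equal noise-prior convolutions and normalize", {
  # Gaussian: closed form at the origin
  expect_equal(evidence_gaussian(0, 0, 1.2, 0.7, 1),
               1 / (2 * pi * sqrt((1 + 1.2^2) * (1 + 0.7^2))))
  # numeric convolution cross-check on a grid of evaluation points
  np <- ray_noise_pdf(1)
  for (pt in list(c(1, 1), c(0.5, 2), c(-2, 0.3))) {
    f <- function(a, b) np(pt[1] - a, pt[2] - b) * dnorm(a, 0, 1) * dnorm(b, 0, 1)
    # integrate piecewise: the noise density has kinks along a = pt1, b = pt2
    conv <- 0
    for (xr in list(c(-10, pt[1]), c(pt[1], 10)))
      for (yr in list(c(-10, pt[2]), c(pt[2], 10)))
        conv <- conv + gl_grid_integral(f, xr[1], xr[2], yr[1], yr[2], n = 200)
    expect_lt(rel_err(evidence_rayleigh(pt[1], pt[2], 1, 1, 1), conv), 1e-5)
  }
  gconv <- gl_grid_integral(function(a, b)
    gauss_noise_pdf(0.8)(1.5 - a, -0.5 - b) * dnorm(a, 0, 2) * dnorm(b, 0, 1),
    -16, 16, -16, 16, n = 400)
  expect_lt(rel_err(evidence_gaussian(1.5, -0.5, 2, 1, 0.8), gconv), 1e-5)
  # both evidences integrate to 1 over the observation plane
  ig <- gl_grid_integral(function(a, b) evidence_gaussian(a, b, 1.2, 0.7, 1),
                         -15, 15, -15, 15, n = 300)
  ir <- gl_grid_integral(function(a, b) evidence_rayleigh(a, b, 1, 1, 1),
                         -15, 15, -15, 15, n = 300)
  expect_lt(abs(ig - 1), 1e-6)
  expect_lt(abs(ir - 1), 1e-6)
  # evenness in each argument
  expect_equal(evidence_rayleigh(-1.3, 0.7, 1, 1, 1),
               evidence_rayleigh(1.3, 0.7, 1, 1, 1))
})

test_that("mixture shrinkage under Gaussian noise matches the oracle", {
  pm <- mixture_params(0.6, 3, 3, 0.5, 0.5)
  np <- gauss_noise_pdf(1)
  pr <- function(a, b) mixture_pdf2(a, b, pm)
  for (y in c(-3, 0.5, 2)) for (yp in c(0, 1.5)) {
    o <- mmse_quadrature_oracle(y, yp, pr, np, 25)
    expect_lt(rel_err(bigauss_mix_shrink(y, yp, pm, 1), o, guard = 1e-6), 1e-5)
  }
  # collapse to Wiener at a = 1; parity in y and yp
  p1 <- mixture_params(1, 3, 3, 0.5, 0.5)
  expect_equal(bigauss_mix_shrink(2, 5, p1, 1),
               wiener_bivariate(2, 5, 3, 3, 1)$child)
  expect_equal(bigauss_mix_shrink(0, 1.2, pm, 1), 0)
  expect_equal(bigauss_mix_shrink(-1.4, 0.8, pm, 1),
               -bigauss_mix_shrink(1.4, 0.8, pm, 1))
  expect_equal(bigauss_mix_shrink(1.4, -0.8, pm, 1),
               bigauss_mix_shrink(1.4, 0.8, pm, 1))
  # large coefficients must not overflow the evidence ratio
  expect_true(is.finite(bigauss_mix_shrink(1e6, 1e6, pm, 1)))
})

test_that("mixture shrinkage under Rayleigh noise matches the oracle", {
  pm <- mixture_params(0.5, 2, 2, 0.4, 0.4)
  np <- ray_noise_pdf(1)
  pr <- function(a, b) mixture_pdf2(a, b, pm)
  for (y in c(0.5, 2)) for (yp in c(0.5, 2)) {
    o <- mmse_quadrature_oracle(y, yp, pr, np, 18)
    expect_lt(rel_err(bigauss_ray_mix_shrink(y, yp, pm, 1), o, 1e-6), 1e-3)
  }
  p1 <- mixture_params(1, 2, 2, 0.4, 0.4)
  expect_equal(bigauss_ray_mix_shrink(1.5, 0.2, p1, 1),
               rayleigh_noise_gauss_prior(1.5, 2, 1))
  expect_equal(bigauss_ray_mix_shrink(0, 1, pm, 1), 0)
  expect_true(is.finite(bigauss_ray_mix_shrink(1e5, 1e5, pm, 1)))
})

test_that("all shrinkages shrink and grow with the prior scale", {
  ys <- seq(-6, 6, by = 0.75)
  pm <- mixture_params(0.4, 2.5, 2, 0.3, 0.3)
  for (y in ys) {
    expect_lte(abs(bigauss_mix_shrink(y, 1, pm, 1)), abs(y) + 1e-12)
    expect_lte(abs(bigauss_ray_mix_shrink(y, 1, pm, 1)), abs(y) + 1e-12)
    expect_lte(abs(rayleigh_noise_gauss_prior(y, 1.7, 0.9)), abs(y) + 1e-12)
  }
  gains <- vapply(c(0.5, 1, 2, 4, 8), function(s)
    bigauss_mix_shrink(1.5, 1, mixture_params(1, s, s, 0.3, 0.3), 1) / 1.5,
    numeric(1))
  expect_true(all(diff(gains) > 0))
  expect_true(all(gains < 1))
})

test_that("the quadrature oracle is internally converged", {
  pm <- mixture_params(0.6, 3, 3, 0.5, 0.5)
  pr <- function(a, b) mixture_pdf2(a, b, pm)
  np <- gauss_noise_pdf(1)
  a <- mmse_quadrature_oracle(1.3, 0.4, pr, np, 25, reltol = 1e-8)
  b <- mmse_quadrature_oracle(1.3, 0.4, pr, np, 25, reltol = 5e-9)
  expect_lt(abs(a - b), 1e-6)
  # odd integrand at y = 0 under symmetric prior and noise
  expect_lt(abs(mmse_quadrature_oracle(0, 2, pr, np, 25)), 1e-9)
})
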