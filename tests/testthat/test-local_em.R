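truth <- mixture_params(0.6, 3, 3, 0.5, 0.5)

test_that("global-window EM recovers mixture parameters from clean pairs", {
  sp <- sample_pairs(truth, 1e5, seed = 42)
  fit <- em_fit_clean(list(child = sp$w1, parent = sp$w2),
                      window_spec("global"), n_iter = 20)
  expect_lt(abs(fit$a[1] - 0.6), 0.05)
  for (f in c("s11", "s12")) expect_lt(abs(fit[[f]][1] / 3 - 1), 0.05)
  for (f in c("s21", "s22")) expect_lt(abs(fit[[f]][1] / 0.5 - 1), 0.05)
  # likelihood trace is non-decreasing
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-1])))
  expect_true(all(fit$a >= 0 & fit$a <= 1))
})

test_that("degenerate all-zero windows hit the variance floor, a unchanged", {
  z <- list(child = rep(0, 50), parent = rep(0, 50))
  fit <- em_fit_clean(z, window_spec("global"), n_iter = 3)
  expect_equal(fit$a[1], 0.5)
  expect_true(all(c(fit$s11, fit$s21) <= 1e-100))
  expect_true(all(c(fit$s11, fit$s21) > 0))
})

test_that("noisy EM: continuity to clean fit and KL-accurate recovery", {
  sp <- sample_pairs(truth, 1e5, seed = 42)
  pairs <- list(child = sp$w1, parent = sp$w2)
  w <- window_spec("global")
  near0 <- em_fit_noisy(pairs, noise_model("gaussian", sigma_n = 1e-9), w,
                        n_iter = 5)
  clean <- em_fit_clean(pairs, w, n_iter = 5)
  for (f in c("a", "s11", "s12", "s21", "s22"))
    expect_lt(max(abs(near0[[f]] - clean[[f]])), 1e-6)

  set.seed(7)
  noisy <- list(child = sp$w1 + rnorm(1e5), parent = sp$w2 + rnorm(1e5))
  fit <- em_fit_noisy(noisy, noise_model("gaussian", sigma_n = 1), w,
                      n_iter = 20)
  fit1 <- mixture_params(fit$a[1], fit$s11[1], fit$s12[1],
                         fit$s21[1], fit$s22[1])
  g <- seq(-12, 12, length.out = 241)
  h <- g[2] - g[1]
  P <- outer(g, g, function(a, b) mixture_pdf2(a, b, truth))
  Q <- outer(g, g, function(a, b) mixture_pdf2(a, b, fit1))
  expect_lt(sum(P * log(P / Q)) * h^2, 0.02)
})

test_that("noisy EM under the Rayleigh evidence converges to sane values", {
  sp <- sample_pairs(truth, 2e4, seed = 44)
  set.seed(45)
  al <- 1 / sqrt(2)  # sigma_n = 1
  n1 <- sample(c(-1, 1), 2e4, TRUE) * sqrt(rexp(2e4, 1 / (2 * al^2)))
  n2 <- sample(c(-1, 1), 2e4, TRUE) * sqrt(rexp(2e4, 1 / (2 * al^2)))
  noisy <- list(child = sp$w1 + n1, parent = sp$w2 + n2)
  fit <- em_fit_noisy(noisy, noise_model("two_sided_rayleigh", alpha = al),
                      window_spec("global"), n_iter = 10)
  expect_lt(abs(fit$a[1] - 0.6), 0.15)
  expect_lt(abs(fit$s11[1] / 3 - 1), 0.15)
})

test_that("windows below the noise floor clip all variances at the floor", {
  set.seed(5)
  small <- list(child = rnorm(1000, sd = 0.05), parent = rnorm(1000, sd = 0.05))
  fit <- em_fit_noisy(small, noise_model("gaussian", sigma_n = 1),
                      window_spec("global"), n_iter = 5)
  expect_true(all(fit$s11 < 1e-4))
  expect_true(all(fit$s21 < 1e-4))
})

test_that("local variance estimate: exact cases and moment consistency", {
  c3 <- list(child = rep(2, 100), parent = rep(-2, 100))
  lv <- local_variance_estimate(c3, window_spec("global"), sigma_n = 0)
  expect_equal(lv[1], 4)
  # below-noise window goes to the floor
  lvf <- local_variance_estimate(c3, window_spec("global"), sigma_n = 10)
  expect_lt(lvf[1], 1e-10)
  set.seed(6)
  big <- list(child = rnorm(1e4, sd = sqrt(5)), parent = rnorm(1e4, sd = sqrt(5)))
  lv2 <- local_variance_estimate(big, window_spec("global"), sigma_n = 1)
  expect_lt(abs(sqrt(lv2[1]) / 2 - 1), 0.03)
})

test_that("square and anisotropic windows agree on equivalent geometry", {
  set.seed(8)
  y <- array(rnorm(20 * 6 * 1), c(20, 6, 1))
  yp <- array(rnorm(20 * 6 * 1), c(20, 6, 1))
  pairs <- list(child = y, parent = yp)
  # a two-ray window along axis 1 with constant length 3 is the 1D box of
  # half-width 2
  field <- structure(list(
    offsets = list(cbind(1:3, 0:2, 0, 0), cbind(1:3, -(0:2), 0, 0)),
    hplus = array(3L, c(20, 6, 1, 2)),
    angles = c(NA, NA), lengths = c(1, 2, 3), R = 2), class = "window_field")
  fa <- em_fit_clean(pairs, window_spec("anisotropic", field = field), 5)
  fs <- em_fit_clean(pairs, window_spec("square", c(2, 0, 0)), 5)
  for (f in c("a", "s11", "s12", "s21", "s22"))
    expect_equal(fa[[f]], fs[[f]], tolerance = 1e-12)
})
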