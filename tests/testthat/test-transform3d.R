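test_that("forward/inverse transform is a perfect-reconstruction pair", {
  set.seed(11)
  for (dims in list(c(16, 16, 16), c(24, 32, 40), c(64, 48, 32))) {
    v <- array(rnorm(prod(dims)), dims)
    p <- forward_dtcwt3d(v, 2)
    w <- inverse_dtcwt3d(p)
    expect_lt(sqrt(sum((w - v)^2) / sum(v^2)), 1e-8)
  }
  # padding path: odd extents are restored to the original shape
  v <- array(rnorm(17 * 21 * 19), c(17, 21, 19))
  w <- inverse_dtcwt3d(forward_dtcwt3d(v, 2))
  expect_equal(dim(w), dim(v))
  expect_lt(sqrt(sum((w - v)^2) / sum(v^2)), 1e-8)
})

test_that("pyramid structure: 28 oriented subbands per scale, halving grids", {
  v <- noise_volume(c(32, 32, 32), 1, 3)
  p <- forward_dtcwt3d(v, 2)
  expect_equal(p$levels, 2L)
  for (j in 1:2) {
    expect_length(p$subbands[[j]], 28L)
    expect_equal(dim(p$subbands[[j]][[1]]), c(32, 32, 32) / 2^j)
    expect_true(all(vapply(p$subbands[[j]], is.complex, logical(1))))
  }
  expect_error(forward_dtcwt3d(matrix(1, 4, 4), 1), "3D")
  v[1] <- NA
  expect_error(forward_dtcwt3d(v, 1), "finite")
})

test_that("inverse transform is linear and respects zeroed subbands", {
  set.seed(4)
  v1 <- array(rnorm(16^3), c(16, 16, 16))
  v2 <- array(rnorm(16^3), c(16, 16, 16))
  p1 <- forward_dtcwt3d(v1, 2)
  p2 <- forward_dtcwt3d(v2, 2)
  ps <- p1
  for (j in 1:2) for (o in 1:28)
    ps$subbands[[j]][[o]] <- p1$subbands[[j]][[o]] + p2$subbands[[j]][[o]]
  for (t in 1:8)
    ps$lowpass_trees[[t]] <- p1$lowpass_trees[[t]] + p2$lowpass_trees[[t]]
  expect_lt(max(abs(inverse_dtcwt3d(ps) -
                      (inverse_dtcwt3d(p1) + inverse_dtcwt3d(p2)))), 1e-10)
  # zero all subbands: reconstruction is the smooth low-pass component only
  pz <- p1
  for (j in 1:2) for (o in 1:28)
    pz$subbands[[j]][[o]] <- pz$subbands[[j]][[o]] * 0
  lp_only <- inverse_dtcwt3d(pz)
  # high-frequency content is gone: much smoother than the input
  expect_lt(sd(diff(lp_only[, 8, 8])), sd(diff(v1[, 8, 8])))
})

test_that("transform is nearly shift invariant, unlike a separable real DWT", {
  v <- noise_volume(c(48, 48, 48), 1, 7)
  p1 <- forward_dtcwt3d(v, 2)
  vs <- v[c(2:48, 1), , ]
  p2 <- forward_dtcwt3d(vs, 2)
  e1 <- subband_energies(p1)
  e2 <- subband_energies(p2)
  expect_lte(max(abs(e2 - e1) / e1), 0.02)

  # comparative check on structured input: a plane reflector (step edge).
  # A critically sampled separable real DWT swings its detail energy between
  # zero and its maximum depending on how the edge falls on the sampling
  # grid; the complex transform's subband energy is essentially unmoved.
  step_vol <- function(p) {
    v <- array(0, c(32, 32, 32))
    v[(p + 1):32, , ] <- 1
    v
  }
  v1 <- step_vol(16)
  v2 <- step_vol(17)
  e_c1 <- sum(subband_energies(forward_dtcwt3d(v1, 1))[1, ])
  e_c2 <- sum(subband_energies(forward_dtcwt3d(v2, 1))[1, ])
  dev_cplx <- abs(e_c2 - e_c1) / max(e_c1, e_c2)
  haar_h1 <- function(x) {
    i1 <- seq(1, 31, by = 2)
    sum(((x[i1, , ] - x[i1 + 1, , ]) / sqrt(2))^2)
  }
  dev_dwt <- abs(haar_h1(v2) - haar_h1(v1)) / max(haar_h1(v1), haar_h1(v2))
  expect_gt(dev_dwt, 0.2)
  expect_lt(dev_cplx, 0.02)
})

test_that("total pyramid energy is a fixed multiple of input energy", {
  v <- noise_volume(c(32, 32, 32), 2, 9)
  p <- forward_dtcwt3d(v, 3)
  etot <- sum(subband_energies(p)) +
    sum(vapply(p$lowpass_trees, function(a) sum(a^2), numeric(1)))
  # eight orthonormal trees: factor 8 (regression value; tolerance set by
  # the printed precision of the q-shift filter coefficients)
  expect_equal(etot / sum(v^2), 8, tolerance = 1e-7)
})

test_that("parent pairing replicates the coarser grid onto the child grid", {
  v <- noise_volume(c(16, 16, 16), 1, 5)
  p <- forward_dtcwt3d(v, 2)
  pf <- pair_with_parent(p, 1, 7)
  expect_equal(dim(pf$parent), dim(pf$child))
  # brute-force index-mapping oracle
  par <- p$subbands[[2]][[7]]
  ok <- TRUE
  for (i in 1:4) for (jj in 1:4) for (k in 1:4) {
    blk <- pf$parent[(2 * i - 1):(2 * i), (2 * jj - 1):(2 * jj),
                     (2 * k - 1):(2 * k)]
    ok <- ok && all(blk == par[i, jj, k])
  }
  expect_true(ok)
  # constant parent subband
  p$subbands[[2]][[3]][] <- 4 + 2i
  expect_true(all(pair_with_parent(p, 1, 3)$parent == 4 + 2i))
  # coarsest scale: error unless self-pairing requested
  expect_error(pair_with_parent(p, 2, 1), "self_pair")
  sp <- pair_with_parent(p, 2, 1, self_pair_coarsest = TRUE)
  expect_identical(sp$parent, sp$child)
})

test_that("pyramids serialize to disk and back", {
  v <- noise_volume(c(16, 16, 16), 1, 13)
  p <- forward_dtcwt3d(v, 2)
  d <- file.path(tempdir(), "pyr")
  write_pyramid(p, d)
  q <- read_pyramid(d)
  expect_equal(q$subbands[[1]][[5]], p$subbands[[1]][[5]])
  w <- inverse_dtcwt3d(q)
  expect_lt(sqrt(sum((w - v)^2) / sum(v^2)), 1e-8)
  unlink(d, recursive = TRUE)
})
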