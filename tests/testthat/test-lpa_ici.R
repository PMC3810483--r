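test_that("directional kernels satisfy their moment conditions", {
  ds <- direction_set("planar_L8")
  k0 <- build_directional_kernels(ds, c(1, 2, 3, 5), poly_order = 0)
  # order 0, h = 3, theta = 0: three collinear voxels, uniform weights
  k <- k0[[1]][[3]]
  expect_equal(nrow(k$offsets), 3)
  expect_true(all(k$offsets[, 2:3] == 0))
  expect_equal(k$weights, rep(1 / 3, 3))
  # every kernel reproduces constants
  const <- array(7, c(12, 12, 4))
  for (di in c(1, 2, 6)) for (si in 1:4) {
    est <- octdespeckle:::apply_kernel(const, k0[[di]][[si]],
                                       array(1, dim(const)))$est
    expect_equal(est[6, 6, 2], 7)
  }
  # order 1 kernels are exact on a linear ramp at interior voxels
  ramp <- array(rep(seq_len(20), times = 400), c(20, 20, 20)) * 0.5 + 3
  k1 <- build_directional_kernels(ds, c(1, 2, 3, 5), poly_order = 1)
  est <- octdespeckle:::apply_kernel(ramp, k1[[1]][[4]],
                                     array(1, dim(ramp)))$est
  expect_lt(max(abs(est - ramp)[8:12, 8:12, 8:12]), 1e-10)
  expect_error(build_directional_kernels(ds, c(3, 2)), "increasing")
})

test_that("ICI rule: worked interval example and limiting behaviours", {
  # intervals [0,2], [1,3], [2.5,4]: D2 = [1,2], D3 empty -> s+ = 2
  expect_equal(ici_select(c(1, 2, 3.25), c(1, 1, 0.75), R = 1), 2L)
  # identical estimates with shrinking stds intersect throughout
  expect_equal(ici_select(rep(1, 5), (5:1) / 5, R = 2), 5L)
  # invariance under joint positive rescaling
  e <- c(1.1, 0.9, 1.4, 2.0)
  s <- c(1, 0.7, 0.5, 0.35)
  expect_equal(ici_select(e, s, 2), ici_select(10 * e, 10 * s, 2))
  expect_error(ici_select(numeric(0), numeric(0), 2), "empty")
})

test_that("window selection expands on smooth fields, contracts at edges", {
  # noise-free constant field: every direction runs to the largest h
  wfc <- select_windows(array(5, c(16, 16, 8)), 1, direction_set(),
                        c(1, 2, 3, 5, 8), R = 2)
  expect_true(all(wfc$hplus == 8))
  # homogeneous noisy field: >= 90% of voxels choose h_J
  set.seed(3)
  f <- array(10 + rnorm(40 * 40 * 8), c(40, 40, 8))
  wf <- select_windows(f, 1, direction_set(), c(1, 2, 3, 5, 8), R = 2)
  expect_gte(mean(wf$hplus == 8), 0.9)
  # step edge: directions crossing the edge select shorter windows than
  # directions running along it, near the edge
  set.seed(4)
  g <- array(0, c(40, 40, 8))
  g[21:40, , ] <- 10
  gn <- g + array(rnorm(length(g)), dim(g))
  ds8 <- direction_set("planar_L8")
  wfe <- select_windows(gn, 1, ds8, c(1, 2, 3, 5, 8), R = 2)
  near <- 19:22
  h_cross <- mean(wfe$hplus[near, , , c(1, 5)])   # 0 and 180 degrees
  h_along <- mean(wfe$hplus[near, , , c(3, 7)])   # 90 and 270 degrees
  expect_lt(h_cross, h_along)
  # star windows on the smooth side are larger than at the edge
  expect_gt(mean(wfe$hplus[5:10, , , ]), mean(wfe$hplus[near, , , ]))
})

test_that("low-pass window lengths map to subband grids by 2^(j-1)", {
  set.seed(9)
  lp <- array(rnorm(8 * 8 * 4, 20, 1), c(8, 8, 4))
  wf <- select_windows(lp, 1, direction_set(), c(1, 2), R = 2)
  # j = 1: lengths unchanged (2^0), grid upsampled 2^(J-1) for J = 2
  s1 <- windows_for_subband(wf, scale = 1, levels = 2,
                            target_dims = c(16, 16, 8), theta = 45)
  expect_equal(sort(unique(as.vector(s1$hplus))),
               sort(unique(as.vector(wf$hplus[, , , c(2, 8, 13, 14)]))))
  # j = 3 with h+ = 2 gives length 8 at the mapped voxel
  wf2 <- wf
  wf2$hplus[] <- 2L
  s3 <- windows_for_subband(wf2, scale = 3, levels = 3,
                            target_dims = c(8, 8, 4), theta = 45)
  expect_true(all(s3$hplus == 8))
  # brute-force index-mapping oracle on one direction of an 8x8 field
  s2 <- windows_for_subband(wf, scale = 2, levels = 2,
                            target_dims = c(8, 8, 4), theta = 45)
  keep_dir <- order(abs(((wf$angles[1:12] - 45) + 90) %% 180 - 90))[1]
  for (i in 1:8) for (j in 1:8) for (k in 1:4) {
    expect_equal(s2$hplus[i, j, k, 1], 2 * wf$hplus[i, j, k, keep_dir])
  }
  # no in-plane orientation: no matching pair
  expect_null(windows_for_subband(wf, 1, 2, c(16, 16, 8), NA))
})

test_that("subband orientation table is scale-free and plausibly oriented", {
  ot <- subband_orientations()
  expect_equal(nrow(ot), 28)
  # orientations come in through-plane mirror pairs with equal angles
  expect_true(all(!is.na(ot$f1)))
  expect_true(all(ot$theta >= 0 & ot$theta < 180, na.rm = TRUE))
})
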