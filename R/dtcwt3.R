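# ---- 1D orthonormal analysis/synthesis filter banks (periodic) -------------
# All 1D operations act on the rows of a matrix so that the 3D routines can
# permute the processed axis to the front and treat the rest as columns.

cshift_rows <- function(X, s) {
  n <- nrow(X)
  X[((seq_len(n) - 1 + s) %% n) + 1, , drop = FALSE]
}

# One level of the periodic analysis bank; rows of X must be even in number.
# lo[m] = sum_t h0[t] x[(2m - t + L) mod n] with L = half the filter length;
# the rows {h0, h1 at all even circular shifts} form an orthonormal basis for
# the dual-tree filters, so the synthesis bank below is simply the adjoint,
# which makes reconstruction exact for any even row count.
afb_rows <- function(X, h0, h1) {
  n <- nrow(X)
  L <- length(h0) %/% 2
  v0 <- 0
  v1 <- 0
  for (t in seq_along(h0)) {
    s <- cshift_rows(X, L - t)
    v0 <- v0 + h0[t] * s
    v1 <- v1 + h1[t] * s
  }
  ev <- seq(2, n, by = 2)
  list(lo = v0[ev, , drop = FALSE], hi = v1[ev, , drop = FALSE])
}

sfb_rows <- function(lo, hi, h0, h1) {
  n <- 2 * nrow(lo)
  L <- length(h0) %/% 2
  ev <- seq(2, n, by = 2)
  u0 <- matrix(0, n, ncol(lo))
  u1 <- matrix(0, n, ncol(hi))
  u0[ev, ] <- lo
  u1[ev, ] <- hi
  y <- 0
  for (t in seq_along(h0)) {
    y <- y + h0[t] * cshift_rows(u0, t - L) + h1[t] * cshift_rows(u1, t - L)
  }
  y
}

# ---- separable 3D level ----------------------------------------------------

afb_dim <- function(a, d, h0, h1) {
  perm <- c(d, setdiff(1:3, d))
  inv <- order(perm)
  ap <- aperm(a, perm)
  dp <- dim(ap)
  r <- afb_rows(matrix(ap, nrow = dp[1]), h0, h1)
  list(lo = aperm(array(r$lo, c(dp[1] / 2, dp[2], dp[3])), inv),
       hi = aperm(array(r$hi, c(dp[1] / 2, dp[2], dp[3])), inv))
}

sfb_dim <- function(lo, hi, d, h0, h1) {
  perm <- c(d, setdiff(1:3, d))
  inv <- order(perm)
  lp <- aperm(lo, perm)
  hp <- aperm(hi, perm)
  dp <- dim(lp)
  y <- sfb_rows(matrix(lp, nrow = dp[1]), matrix(hp, nrow = dp[1]), h0, h1)
  aperm(array(y, c(2 * dp[1], dp[2], dp[3])), inv)
}

# one separable analysis level for one tree; f is a list of three lo/hi pairs
# subband pattern index q in 1..7 encodes which axes are highpass:
# q = b1*4 + b2*2 + b3 with b_d = 1 when axis d is highpass.
afb3d <- function(x, f) {
  hi <- vector("list", 7)
  s1 <- afb_dim(x, 1, f[[1]]$lo, f[[1]]$hi)
  lo <- NULL
  for (b1 in 0:1) {
    a1 <- if (b1) s1$hi else s1$lo
    s2 <- afb_dim(a1, 2, f[[2]]$lo, f[[2]]$hi)
    for (b2 in 0:1) {
      a2 <- if (b2) s2$hi else s2$lo
      s3 <- afb_dim(a2, 3, f[[3]]$lo, f[[3]]$hi)
      for (b3 in 0:1) {
        q <- b1 * 4 + b2 * 2 + b3
        if (q == 0) lo <- s3$lo else hi[[q]] <- if (b3) s3$hi else s3$lo
      }
    }
  }
  list(lo = lo, hi = hi)
}

sfb3d <- function(lo, hi, f) {
  pick <- function(b1, b2, b3) {
    q <- b1 * 4 + b2 * 2 + b3
    if (q == 0) lo else hi[[q]]
  }
  a1 <- vector("list", 2)
  for (b1 in 0:1) {
    a2 <- vector("list", 2)
    for (b2 in 0:1) {
      a2[[b2 + 1]] <- sfb_dim(pick(b1, b2, 0), pick(b1, b2, 1), 3,
                              f[[3]]$lo, f[[3]]$hi)
    }
    a1[[b1 + 1]] <- sfb_dim(a2[[1]], a2[[2]], 2, f[[2]]$lo, f[[2]]$hi)
  }
  sfb_dim(a1[[1]], a1[[2]], 1, f[[1]]$lo, f[[1]]$hi)
}

# ---- tree combination ------------------------------------------------------
# Trees are indexed by (m, n, p) in {1,2}^3: which of the two filter banks is
# used along each axis.  Writing the per-axis complex wavelet as
# psi = psi_1 + i psi_2 (tree 2 approximates the Hilbert transform of tree 1),
# the product wavelet psi(x1) psi(x2) psi(x3) with conjugation pattern
# (e1, e2, e3) in {+1, -1}^3 has
#   Re = u111 - e2 e3 u122 - e1 e3 u212 - e1 e2 u221
#   Im = e1 u211 + e2 u121 + e3 u112 - e1 e2 e3 u222
# over the tree subbands u_{mnp}.  Four sign patterns give four distinct
# orientations per highpass type (the other four are complex conjugates),
# hence 7 x 4 = 28 oriented complex subbands per scale.  The 4x4 weight
# matrices (entries +-1/2) are orthonormal, so the combination is invertible
# by its transpose and preserves energy.

comb_matrices <- function() {
  E <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  A <- t(apply(E, 1, function(e) c(1, -e[2] * e[3], -e[1] * e[3], -e[1] * e[2]))) / 2
  B <- t(apply(E, 1, function(e) c(e[1], e[2], e[3], -e[1] * e[2] * e[3]))) / 2
  # tree labels (m, n, p) contributing to the real / imaginary groups
  list(A = A, B = B,
       even = rbind(c(1, 1, 1), c(1, 2, 2), c(2, 1, 2), c(2, 2, 1)),
       odd  = rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2), c(2, 2, 2)))
}

tree_index <- function(m, n, p) (m - 1) * 4 + (n - 1) * 2 + p

#' Forward 3D dual-tree complex wavelet transform
#'
#' Decomposes a real 3D volume into `levels` scales of 28 oriented complex
#' subbands plus a low-pass residual.  The transform is formed from eight
#' critically sampled orthonormal separable wavelet transforms (one per
#' combination of the two dual-tree filter banks along the three axes) whose
#' subbands are combined orthonormally into oriented complex subbands.  It is
#' exactly invertible by [inverse_dtcwt3d()] and nearly shift invariant.
#'
#' Axes whose extent is not divisible by `2^levels` are reflection-padded at
#' the trailing end; the inverse crops back to the original extent.  Filters
#' are orthonormal, so white image-domain noise of standard deviation
#' `sigma` produces wavelet coefficients (real and imaginary parts alike)
#' with standard deviation `sigma` at every scale.
#'
#' @param volume numeric 3D array of finite values.
#' @param levels integer number of decomposition scales (>= 1).
#' @return An object of class `complex_pyramid`: a list with `levels`,
#'   `subbands` (per scale, a list of 28 complex arrays; subband index
#'   `o = (q - 1) * 4 + c` for highpass pattern `q` in 1..7 and orientation
#'   `c` in 1..4), `lowpass` (mean of the eight tree residuals),
#'   `lowpass_trees` (the eight tree residuals, needed for exact inversion),
#'   and the original and padded extents.
#' @seealso [inverse_dtcwt3d()], [pair_with_parent()]
#' @export
forward_dtcwt3d <- function(volume, levels = 3L) {
  if (length(dim(volume)) != 3L)
    stop("`volume` must be a 3D array")
  if (!all(is.finite(volume)))
    stop("`volume` must contain only finite values")
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  dims <- dim(volume)
  block <- 2L^levels
  pad_dims <- as.integer(ceiling(dims / block) * block)
  x <- pad_reflect(volume, pad_dims)

  fb <- dt_filter_bank()
  trees <- vector("list", 8)          # per tree: list of per-level hi lists
  lows <- vector("list", 8)
  for (m in 1:2) for (n in 1:2) for (p in 1:2) {
    lo <- x
    hi_j <- vector("list", levels)
    for (j in seq_len(levels)) {
      bank <- if (j == 1L) fb$first else fb$qshift
      f <- list(bank[[m]], bank[[n]], bank[[p]])
      r <- afb3d(lo, f)
      lo <- r$lo
      hi_j[[j]] <- r$hi
    }
    ti <- tree_index(m, n, p)
    trees[[ti]] <- hi_j
    lows[[ti]] <- lo
  }

  cm <- comb_matrices()
  subbands <- vector("list", levels)
  for (j in seq_len(levels)) {
    # the first-stage trees realize psi_2 ~ -H(psi_1) while the q-shift
    # cascade realizes +H, so the imaginary part is negated at scale 1 to
    # keep every scale's complex wavelet (near-)analytic with one convention
    isg <- if (j == 1L) -1 else 1
    sb <- vector("list", 28)
    for (q in 1:7) {
      ue <- lapply(1:4, function(r) {
        t3 <- cm$even[r, ]
        trees[[tree_index(t3[1], t3[2], t3[3])]][[j]][[q]]
      })
      uo <- lapply(1:4, function(r) {
        t3 <- cm$odd[r, ]
        trees[[tree_index(t3[1], t3[2], t3[3])]][[j]][[q]]
      })
      for (cc in 1:4) {
        re <- cm$A[cc, 1] * ue[[1]] + cm$A[cc, 2] * ue[[2]] +
          cm$A[cc, 3] * ue[[3]] + cm$A[cc, 4] * ue[[4]]
        im <- cm$B[cc, 1] * uo[[1]] + cm$B[cc, 2] * uo[[2]] +
          cm$B[cc, 3] * uo[[3]] + cm$B[cc, 4] * uo[[4]]
        sb[[(q - 1) * 4 + cc]] <- re + (1i * isg) * im
      }
    }
    subbands[[j]] <- sb
  }

  lp <- Reduce(`+`, lows) / 8
  structure(list(levels = levels, subbands = subbands,
                 lowpass = lp, lowpass_trees = lows,
                 dims = dims, pad_dims = pad_dims),
            class = "complex_pyramid")
}

#' Inverse 3D dual-tree complex wavelet transform
#'
#' Reconstructs the volume from a [forward_dtcwt3d()] pyramid.  The oriented
#' complex subbands are split back into the eight tree subbands by the
#' transposed combination matrices, each tree is inverted with its synthesis
#' bank, and the eight reconstructions are averaged.  For an unmodified
#' pyramid this reproduces the input to machine precision; the result is
#' cropped to the original extents if padding was applied.
#'
#' @param pyramid a `complex_pyramid` object.
#' @return numeric 3D array with the pyramid's original extents.
#' @export
inverse_dtcwt3d <- function(pyramid) {
  stopifnot(inherits(pyramid, "complex_pyramid"))
  fb <- dt_filter_bank()
  cm <- comb_matrices()
  J <- pyramid$levels
  for (j in seq_len(J)) {
    de <- dim(pyramid$subbands[[j]][[1]])
    if (!all(vapply(pyramid$subbands[[j]], function(s)
      identical(dim(s), de), logical(1))))
      stop("mutually inconsistent subband extents at scale ", j)
  }
  # redistribute complex subbands to tree subbands
  trees <- vector("list", 8)
  for (ti in 1:8) trees[[ti]] <- vector("list", J)
  for (j in seq_len(J)) {
    isg <- if (j == 1L) -1 else 1
    for (ti in 1:8) trees[[ti]][[j]] <- vector("list", 7)
    for (q in 1:7) {
      res <- lapply(1:4, function(cc) Re(pyramid$subbands[[j]][[(q - 1) * 4 + cc]]))
      ims <- lapply(1:4, function(cc) isg * Im(pyramid$subbands[[j]][[(q - 1) * 4 + cc]]))
      for (r in 1:4) {
        ue <- cm$A[1, r] * res[[1]] + cm$A[2, r] * res[[2]] +
          cm$A[3, r] * res[[3]] + cm$A[4, r] * res[[4]]
        uo <- cm$B[1, r] * ims[[1]] + cm$B[2, r] * ims[[2]] +
          cm$B[3, r] * ims[[3]] + cm$B[4, r] * ims[[4]]
        te <- cm$even[r, ]
        to <- cm$odd[r, ]
        trees[[tree_index(te[1], te[2], te[3])]][[j]][[q]] <- ue
        trees[[tree_index(to[1], to[2], to[3])]][[j]][[q]] <- uo
      }
    }
  }
  out <- 0
  for (m in 1:2) for (n in 1:2) for (p in 1:2) {
    ti <- tree_index(m, n, p)
    lo <- pyramid$lowpass_trees[[ti]]
    for (j in rev(seq_len(J))) {
      bank <- if (j == 1L) fb$first else fb$qshift
      f <- list(bank[[m]], bank[[n]], bank[[p]])
      lo <- sfb3d(lo, trees[[ti]][[j]], f)
    }
    out <- out + lo
  }
  out <- out / 8
  d <- pyramid$dims
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
}

# reflection padding of the trailing end of each axis up to `target` extents
pad_reflect <- function(x, target) {
  d <- dim(x)
  for (ax in 1:3) {
    extra <- target[ax] - dim(x)[ax]
    if (extra > 0) {
      n <- dim(x)[ax]
      if (extra > n)
        stop("axis ", ax, " too short (", n, ") for the requested padding")
      idx <- c(seq_len(n), seq(n, by = -1, length.out = extra))
      x <- switch(ax,
                  x[idx, , , drop = FALSE],
                  x[, idx, , drop = FALSE],
                  x[, , idx, drop = FALSE])
    }
  }
  x
}

#' Pair subband coefficients with their parents
#'
#' For an oriented subband at scale `scale`, returns the aligned child/parent
#' coefficient grids: the parent is the same-orientation subband at the next
#' coarser scale, upsampled by nearest-neighbour replication (each parent
#' value covers a 2x2x2 child block) so that both grids have identical
#' extents.  Coefficients at the coarsest scale have no parent; with
#' `self_pair_coarsest = TRUE` they are paired with themselves, which reduces
#' the bivariate machinery to its univariate form.
#'
#' @param pyramid a `complex_pyramid`.
#' @param scale integer scale index (1 = finest).
#' @param orientation integer subband index in 1..28.
#' @param self_pair_coarsest logical; allow `scale == levels` by self-pairing.
#' @return A list of class `pair_field` with complex arrays `child` and
#'   `parent` of identical dimension, plus `scale` and `orientation`.
#' @export
pair_with_parent <- function(pyramid, scale, orientation,
                             self_pair_coarsest = FALSE) {
  stopifnot(inherits(pyramid, "complex_pyramid"))
  J <- pyramid$levels
  if (orientation < 1 || orientation > 28) stop("`orientation` must be in 1..28")
  if (scale < 1 || scale > J) stop("`scale` must be in 1..", J)
  child <- pyramid$subbands[[scale]][[orientation]]
  if (scale == J) {
    if (!self_pair_coarsest)
      stop("scale ", J, " has no parent; set `self_pair_coarsest = TRUE`")
    parent <- child
  } else {
    parent <- upsample_nn(pyramid$subbands[[scale + 1]][[orientation]],
                          dim(child))
  }
  structure(list(child = child, parent = parent,
                 scale = scale, orientation = orientation),
            class = "pair_field")
}

# nearest-neighbour 2x replication per axis, cropped to `target`
upsample_nn <- function(a, target) {
  a[ceiling(seq_len(target[1]) / 2),
    ceiling(seq_len(target[2]) / 2),
    ceiling(seq_len(target[3]) / 2), drop = FALSE]
}

#' Total subband energy of a pyramid
#'
#' Sum of squared coefficient magnitudes, per scale and orientation.
#'
#' @param pyramid a `complex_pyramid`.
#' @return matrix of energies, `levels` rows x 28 columns.
#' @export
subband_energies <- function(pyramid) {
  J <- pyramid$levels
  e <- matrix(0, J, 28)
  for (j in seq_len(J)) for (o in 1:28)
    e[j, o] <- sum(Mod(pyramid$subbands[[j]][[o]])^2)
  e
}

#' @export
print.complex_pyramid <- function(x, ...) {
  cat("3D dual-tree complex wavelet pyramid\n")
  cat("  levels:", x$levels, " input:", paste(x$dims, collapse = "x"),
      " padded:", paste(x$pad_dims, collapse = "x"), "\n")
  for (j in seq_len(x$levels))
    cat("  scale", j, ": 28 subbands of",
        paste(dim(x$subbands[[j]][[1]]), collapse = "x"), "\n")
  invisible(x)
}
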