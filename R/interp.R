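# Low-level numerical kernels shared by the phantom generator and the
# preprocessing chain: separable Gaussian blur, per-frame bilinear
# translation, and quintic B-spline interpolation (prefilter + evaluation)
# for the rotation resampling step.

# ---- separable Gaussian blur ------------------------------------------------

# Blur a 3D array along one axis with a normalized discrete Gaussian kernel,
# zero-padded at the borders. sigma is in voxels.
blur_axis <- function(a, sigma, axis) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (j in seq(-r, r)) {
    src <- seq_len(n) - j
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst <- which(keep)
    org <- src[keep]
    wj <- w[j + r + 1L]
    if (axis == 1L) {
      out[dst, , ] <- out[dst, , ] + wj * a[org, , ]
    } else if (axis == 2L) {
      out[, dst, ] <- out[, dst, ] + wj * a[, org, ]
    } else {
      out[, , dst] <- out[, , dst] + wj * a[, , org]
    }
  }
  out
}

# Anisotropic Gaussian blur; fwhm in µm per axis, spacing in µm per axis.
# FWHM = 2 sqrt(2 ln 2) sigma. Compiled separable convolution; blur_axis
# above is the plain-R reference used to cross-check it.
gauss_blur3d <- function(a, fwhm_um, spacing_um) {
  sigma_vox <- (fwhm_um / (2 * sqrt(2 * log(2)))) / spacing_um
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    a <- array(conv_axis3d(as.numeric(a), d, w, ax), d)
  }
  a
}

# ---- frame translation ------------------------------------------------------

# Translate a 2D matrix by (dy, dz) (content moves toward higher indices for
# positive offsets), bilinear interpolation, zero fill outside.
shift_frame2d <- function(M, dy, dz) {
  iy <- floor(dy); fy <- dy - iy
  iz <- floor(dz); fz <- dz - iz
  w <- c((1 - fy) * (1 - fz), fy * (1 - fz), (1 - fy) * fz, fy * fz)
  oy <- c(iy, iy + 1, iy, iy + 1)
  oz <- c(iz, iz, iz + 1, iz + 1)
  ny <- nrow(M); nz <- ncol(M)
  out <- matrix(0, ny, nz)
  for (k in 1:4) {
    if (w[k] == 0) next
    sy <- seq_len(ny) - oy[k]
    sz <- seq_len(nz) - oz[k]
    ky <- sy >= 1 & sy <= ny
    kz <- sz >= 1 & sz <= nz
    if (!any(ky) || !any(kz)) next
    out[which(ky), which(kz)] <- out[which(ky), which(kz)] +
      w[k] * M[sy[ky], sz[kz], drop = FALSE]
  }
  out
}

# Integer shift of matrix rows/columns with zero fill: out[i] = in[i - s].
shift_rows_int <- function(M, s) {
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  src <- seq_len(n) - s
  keep <- src >= 1 & src <= n
  if (any(keep)) out[which(keep), ] <- M[src[keep], ]
  out
}
shift_cols_int <- function(M, s) {
  n <- ncol(M)
  out <- matrix(0, nrow(M), n)
  src <- seq_len(n) - s
  keep <- src >= 1 & src <= n
  if (any(keep)) out[, which(keep)] <- M[, src[keep]]
  out
}

# Translate every YZ frame of a 3D array by per-frame voxel offsets, using
# quintic B-spline interpolation (the volume is prefiltered once along Y
# and Z; each frame then needs only a separable 6-tap evaluation). Ringing
# may produce small negative values; callers clamp at zero.
# offsets: matrix n_x rows, columns (dy, dz).
shift_frames <- function(a, offsets) {
  d <- dim(a)
  stopifnot(nrow(offsets) == d[1])
  if (all(offsets == 0)) return(a)
  if (all(offsets == round(offsets))) {
    # integer offsets: exact zero-fill translation, no prefilter needed
    out <- array(0, d)
    for (x in seq_len(d[1])) {
      dy <- offsets[x, 1]; dz <- offsets[x, 2]
      if (dy == 0 && dz == 0) {
        out[x, , ] <- a[x, , ]
      } else {
        out[x, , ] <- shift_cols_int(shift_rows_int(a[x, , ], dy), dz)
      }
    }
    return(out)
  }
  c3 <- bspline_prefilter_axis(bspline_prefilter_axis(a, 2L), 3L)
  array(spline_shift_frames(as.numeric(c3), d, offsets), d)
}

# ---- quintic B-spline interpolation ----------------------------------------

# Centered B-spline basis of order 5, support (-3, 3).
bspline5 <- function(x) {
  a <- abs(x)
  out <- numeric(length(a))
  i1 <- a < 1
  i2 <- !i1 & a < 2
  i3 <- !i1 & !i2 & a < 3
  a1 <- a[i1]; a2 <- a[i2]; a3 <- a[i3]
  out[i1] <- (66 - 60 * a1^2 + 30 * a1^4 - 10 * a1^5) / 120
  out[i2] <- (51 + 75 * a2 - 210 * a2^2 + 150 * a2^3 - 45 * a2^4 + 5 * a2^5) / 120
  out[i3] <- (3 - a3)^5 / 120
  out
}

# Poles (roots inside the unit circle) of the quintic B-spline z-transform,
# computed from its integer samples (1, 26, 66, 26, 1)/120.
bspline5_poles <- function() {
  r <- polyroot(c(1, 26, 66, 26, 1))
  p <- Re(r[abs(r) < 1])
  sort(p)
}

# Direct B-spline transform (prefilter) along the rows of a matrix, so that
# sum_k c[k] beta5(x - k) interpolates the samples. Mirror end conditions.
bspline_prefilter_mat <- function(M, poles = bspline5_poles(), tol = 1e-12) {
  n <- nrow(M)
  if (n == 1L) return(M)
  gain <- prod((1 - poles) * (1 - 1 / poles))
  M <- M * gain
  for (z in poles) {
    K <- min(n, as.integer(ceiling(log(tol) / log(abs(z)))))
    zk <- z^(seq_len(K) - 1)
    M[1, ] <- zk %*% M[seq_len(K), , drop = FALSE]
    M <- ar1_forward(M, z)
    M[n, ] <- (z / (z * z - 1)) * (M[n, ] + z * M[n - 1, ])
    M <- ar1_backward(M, z)
  }
  M
}

# Prefilter a 3D array along a given axis.
bspline_prefilter_axis <- function(a, axis) {
  d <- dim(a)
  if (d[axis] == 1L) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  m <- bspline_prefilter_mat(m)
  ap <- array(m, dp)
  aperm(ap, order(perm))
}

# Sample prefiltered 2D coefficients (with a 3-voxel zero pad on each side)
# at fractional coordinates, quintic kernel. cpad: padded coefficient matrix;
# sx, sz: coordinate vectors in the unpadded index frame (same length).
bspline5_sample_pad2d <- function(cpad, sx, sz) {
  ix <- floor(sx); iz <- floor(sz)
  out <- numeric(length(sx))
  np1 <- nrow(cpad)
  # padded index of offset k (k = -2..3): ix + k + 3
  for (k in -2:3) {
    wx <- bspline5(sx - (ix + k))
    px <- pmin(pmax(ix + k + 3L, 1L), np1)
    for (l in -2:3) {
      wz <- bspline5(sz - (iz + l))
      pz <- pmin(pmax(iz + l + 3L, 1L), ncol(cpad))
      out <- out + wx * wz * cpad[cbind(px, pz)]
    }
  }
  out
}
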