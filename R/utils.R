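# Shared array helpers: separable Gaussian smoothing, trilinear shifting,
# robust noise estimation. Internal, not exported.

gauss_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with a symmetric kernel, replicate edges
conv_axis3 <- function(a, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(a * k)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # clamped (replicated) edges
    sl <- switch(axis,
                 a[src, , , drop = FALSE],
                 a[, src, , drop = FALSE],
                 a[, , src, drop = FALSE])
    out <- out + k[j] * sl
  }
  out
}

gauss_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3)
  for (ax in 1:3) {
    if (sigma[ax] > 0) a <- conv_axis3(a, gauss_kernel_1d(sigma[ax]), ax)
  }
  a
}

# shift a 3D volume by (dz, dy, dx) voxels (value at output voxel v comes
# from input position v - shift), trilinear interpolation, `fill` outside
shift_volume <- function(vol, shift, fill = stats::median(vol)) {
  d <- dim(vol)
  if (all(shift == 0)) return(vol)
  src <- lapply(1:3, function(ax) seq_len(d[ax]) - shift[ax])
  lo <- lapply(src, floor)
  fr <- lapply(1:3, function(ax) src[[ax]] - lo[[ax]])
  out <- array(0, d)
  wsum <- array(0, d)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    iz <- lo[[1]] + bz; iy <- lo[[2]] + by; ix <- lo[[3]] + bx
    wz <- if (bz == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (by == 0) 1 - fr[[2]] else fr[[2]]
    wx <- if (bx == 0) 1 - fr[[3]] else fr[[3]]
    okz <- iz >= 1 & iz <= d[1]
    oky <- iy >= 1 & iy <= d[2]
    okx <- ix >= 1 & ix <= d[3]
    w <- outer(outer(wz * okz, wy * oky), wx * okx)
    izc <- pmin(pmax(iz, 1L), d[1])
    iyc <- pmin(pmax(iy, 1L), d[2])
    ixc <- pmin(pmax(ix, 1L), d[3])
    out <- out + w * vol[izc, iyc, ixc, drop = FALSE]
    wsum <- wsum + w
  }
  out + (1 - wsum) * fill
}

# robust noise level of a trace: scaled MAD of first differences; the /sqrt(2)
# undoes the variance doubling of differencing
robust_noise <- function(trace) {
  dtr <- diff(trace)
  1.4826 * stats::median(abs(dtr - stats::median(dtr))) / sqrt(2)
}

# peak SNR of a trace: (max - median) / robust noise; 0 when flat
peak_snr <- function(trace) {
  s <- robust_noise(trace)
  num <- max(trace) - stats::median(trace)
  if (s == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / s
}

# md5 of an R object via a temporary serialized file (offline-safe checksum)
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
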