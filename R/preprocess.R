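#' Median bleach correction
#'
#' Divides every volume by its own spatial median, so slow multiplicative
#' intensity loss (photobleaching) is removed and the spatial median of each
#' output volume is exactly 1.
#'
#' @param movie a [movie4d()], every volume with strictly positive median.
#' @return A [movie4d()] of per-median-normalized volumes.
#' @export
bleach_correct <- function(movie) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  out <- movie$data
  for (t in seq_len(d[1])) {
    m <- stats::median(out[t, , , ])
    if (m <= 0) stop("volume ", t, " has non-positive spatial median; ",
                     "cannot bleach-correct a degenerate frame")
    out[t, , , ] <- out[t, , , ] / m
  }
  new_movie4d(out, movie$meta)
}

# index permutation mapping each FFT coefficient to its complex conjugate
conj_flip_index <- function(n) c(1L, rev(seq_len(n - 1L) + 1L))

#' Spatial-Fourier temporal-variance filter
#'
#' Light-sheet stripe shadows and out-of-focus background occupy compact,
#' temporally flickering regions of the spatial-frequency domain, whereas
#' nearly point-like neurons spread over all frequencies. The filter takes
#' the 3D FFT of every volume, computes the temporal variance of each
#' complex coefficient, `E|f - E f|^2`, and zeroes — for all time points —
#' every coefficient whose variance is at or above the stated quantile of
#' the variance map (strictly-below variances are kept, and zero-variance
#' coefficients are always kept). The inverse transform restores a real
#' movie of the original shape.
#'
#' The variance map is Hermitian-symmetric (conjugate coefficients have
#' equal variance), so the kept set is symmetric and the output real; the
#' map is explicitly symmetrized against floating-point noise. The quantile
#' uses the default linear-interpolation estimator (`stats::quantile`
#' type 7) over the full coefficient set. Because quantiles commute with
#' monotone maps, thresholding `var` at its q-quantile and `log10(var)` at
#' the q-quantile of `log10(var)` select the same coefficients.
#'
#' @param movie a [movie4d()] with at least 2 volumes.
#' @param quantile variance quantile above which coefficients are removed
#'   (default 0.99: the top 1% most temporally variable coefficients).
#' @return List with `movie` (filtered [movie4d()]) and `mask` (a
#'   `fourier_mask`: logical keep-array over `(z, y, x)` frequencies, the
#'   variance map, and the quantile used).
#' @export
fourier_filter <- function(movie, quantile = 0.99) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  if (d[1] < 2) stop("fourier_filter needs at least 2 time points ",
                     "(temporal variance is undefined for one)")
  dims <- d[2:4]
  nv <- prod(dims)
  f <- matrix(0i, nv, d[1])
  for (t in seq_len(d[1])) {
    f[, t] <- as.vector(stats::fft(movie$data[t, , , ]))
  }
  mu <- rowMeans(f)
  v <- rowMeans(abs(f - mu)^2)
  vmap <- array(v, dims)
  # symmetrize: conjugate coefficients are equal-variance up to float noise
  flip <- as.vector(array(seq_len(nv), dims)[conj_flip_index(dims[1]),
                                             conj_flip_index(dims[2]),
                                             conj_flip_index(dims[3])])
  vmap <- (vmap + array(v[flip], dims)) / 2
  q <- stats::quantile(vmap, quantile, names = FALSE)
  keep <- (vmap < q) | (vmap == 0)
  kv <- as.vector(keep)
  out <- array(0, d)
  for (t in seq_len(d[1])) {
    ft <- array(f[, t] * kv, dims)
    out[t, , , ] <- Re(stats::fft(ft, inverse = TRUE)) / nv
  }
  # filtered movies may carry small negative excursions; they are kept
  # (zero-clipping would rectify the removed modes into spurious structure)
  mask <- structure(list(keep = keep, variance = vmap, quantile = quantile,
                         threshold = q),
                    class = "fourier_mask")
  list(movie = new_movie4d(out, movie$meta), mask = mask)
}

#' Apply a previously computed Fourier mask to a movie
#'
#' Zeroes the masked spatial-frequency coefficients of every volume.
#' Applying the same mask twice is idempotent.
#'
#' @param movie a [movie4d()].
#' @param mask a `fourier_mask` from [fourier_filter()].
#' @return A filtered [movie4d()].
#' @export
apply_fourier_mask <- function(movie, mask) {
  stopifnot(inherits(movie, "movie4d"), inherits(mask, "fourier_mask"))
  d <- dim(movie$data)
  if (!identical(dim(mask$keep), d[2:4])) {
    stop("mask shape does not match movie volumes")
  }
  kv <- as.vector(mask$keep)
  nv <- prod(d[2:4])
  out <- array(0, d)
  for (t in seq_len(d[1])) {
    ft <- as.vector(stats::fft(movie$data[t, , , ])) * kv
    out[t, , , ] <- Re(stats::fft(array(ft, d[2:4]), inverse = TRUE)) / nv
  }
  new_movie4d(out, movie$meta)
}
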