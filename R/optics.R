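#' Fit a 1D Gaussian profile
#'
#' Least-squares fit of `y = d + A exp(-(x - x0)^2 / (2 sigma^2))`
#' (Levenberg-Marquardt), the standard model for bead intensity profiles.
#' Initialized from the data: `d = min(y)`, `A = max(y) - min(y)`,
#' `x0 = x[argmax]`, `sigma` from the second moment of `y - d`.
#'
#' @param x,y numeric samples (at least 5, non-constant).
#' @return List of class `gaussian1d_fit`: `d`, `A`, `x0`, `sigma`
#'   (positive), `residual` (RMS), `fitted`.
#' @export
fit_gaussian_1d <- function(x, y) {
  if (length(x) < 5 || length(y) != length(x)) {
    stop("need at least 5 (x, y) samples")
  }
  if (max(y) == min(y)) stop("degenerate (constant) profile")
  d0 <- min(y)
  A0 <- max(y) - d0
  x0 <- x[which.max(y)]
  wpos <- pmax(y - d0, 0)
  s0 <- sqrt(sum(wpos * (x - x0)^2) / max(sum(wpos), 1e-12))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 4
  res_fn <- function(p) {
    y - (p[1] + p[2] * exp(-(x - p[3])^2 / (2 * p[4]^2)))
  }
  fit <- minpack.lm::nls.lm(par = c(d0, A0, x0, s0), fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  if (fit$info == 0 || any(!is.finite(p))) {
    stop("1D Gaussian fit did not converge (info = ", fit$info, ")")
  }
  structure(list(d = p[1], A = p[2], x0 = p[3], sigma = abs(p[4]),
                 residual = sqrt(mean(res_fn(p)^2)),
                 fitted = y - res_fn(p)),
            class = "gaussian1d_fit")
}

#' Fit a 2D (elliptical, optionally rotated) Gaussian
#'
#' Least-squares fit of
#' `f(x, y) = d + A exp(-(a (x-x0)^2 + 2 b (x-x0)(y-y0) + c (y-y0)^2))`
#' where `a`, `b`, `c` are built from the widths `sigma_x`, `sigma_y` and
#' the rotation angle `theta` (so their consistency holds by construction):
#' `a = cos^2(theta)/(2 sx^2) + sin^2(theta)/(2 sy^2)`,
#' `b = -sin(2 theta)/(4 sx^2) + sin(2 theta)/(4 sy^2)`,
#' `c = sin^2(theta)/(2 sx^2) + cos^2(theta)/(2 sy^2)`.
#' With `fix_theta_zero = TRUE` the axis-aligned form
#' `d + A exp(-((x-x0)^2/(2 sx^2) + (y-y0)^2/(2 sy^2)))` is fitted.
#'
#' @param image numeric matrix, first dimension along x, second along y.
#' @param x,y coordinate grids for the two dimensions (defaults: 0-based
#'   pixel indices).
#' @param fix_theta_zero fit the axis-aligned form (default `TRUE`).
#' @return List of class `gaussian2d_fit`: `d`, `A`, `x0`, `y0`,
#'   `sigma_x`, `sigma_y`, `theta`, derived `a`, `b`, `c`, `residual`.
#' @export
fit_gaussian_2d <- function(image, x = seq_len(nrow(image)) - 1,
                            y = seq_len(ncol(image)) - 1,
                            fix_theta_zero = TRUE) {
  if (length(image) < 7) stop("need at least 7 samples")
  if (max(image) == min(image)) stop("degenerate (constant) image")
  X <- matrix(x, nrow(image), ncol(image))
  Y <- matrix(y, nrow(image), ncol(image), byrow = TRUE)
  d0 <- min(image)
  A0 <- max(image) - d0
  pk <- which(image == max(image), arr.ind = TRUE)[1, ]
  x00 <- x[pk[1]]
  y00 <- y[pk[2]]
  w <- pmax(image - d0, 0)
  sx0 <- sqrt(sum(w * (X - x00)^2) / max(sum(w), 1e-12))
  sy0 <- sqrt(sum(w * (Y - y00)^2) / max(sum(w), 1e-12))
  if (!is.finite(sx0) || sx0 <= 0) sx0 <- diff(range(x)) / 4
  if (!is.finite(sy0) || sy0 <= 0) sy0 <- diff(range(y)) / 4
  model <- function(p) {
    sx <- p[5]; sy <- p[6]
    th <- if (fix_theta_zero) 0 else p[7]
    a <- cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2)
    b <- -sin(2 * th) / (4 * sx^2) + sin(2 * th) / (4 * sy^2)
    cc <- sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2)
    p[1] + p[2] * exp(-(a * (X - p[3])^2 + 2 * b * (X - p[3]) * (Y - p[4]) +
                          cc * (Y - p[4])^2))
  }
  par0 <- c(d0, A0, x00, y00, sx0, sy0)
  if (!fix_theta_zero) par0 <- c(par0, 0)
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(p) as.numeric(image - model(p)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  if (fit$info == 0 || any(!is.finite(p))) {
    stop("2D Gaussian fit did not converge (info = ", fit$info, ")")
  }
  sx <- abs(p[5]); sy <- abs(p[6])
  th <- if (fix_theta_zero) 0 else p[7]
  structure(list(d = p[1], A = p[2], x0 = p[3], y0 = p[4],
                 sigma_x = sx, sigma_y = sy, theta = th,
                 a = cos(th)^2 / (2 * sx^2) + sin(th)^2 / (2 * sy^2),
                 b = -sin(2 * th) / (4 * sx^2) + sin(2 * th) / (4 * sy^2),
                 c = sin(th)^2 / (2 * sx^2) + cos(th)^2 / (2 * sy^2),
                 residual = sqrt(mean((image - model(fit$par))^2))),
            class = "gaussian2d_fit")
}

#' Beam widths along the propagation axis
#'
#' Fits every transversal illumination profile with an axis-aligned 2D
#' Gaussian and collects the fitted widths: `w(x) = 2 sigma_x`, the 1/e^2
#' beam radius. Profiles whose fit fails are recorded as missing and
#' excluded.
#'
#' @param images list of 2D profiles (first dimension along the sheet
#'   normal).
#' @param positions propagation-axis positions of the profiles,
#'   micrometres, strictly increasing; at least 3.
#' @param pixel_size micrometres per pixel of the profile images.
#' @param wavelength,n optional illumination wavelength (um) and
#'   refractive index, carried along for [rayleigh_length()].
#' @return List of class `beam_profile_series`: `positions`, `sigma_x`,
#'   `w` (= 2 sigma_x), `ok` (fit success flags), `wavelength`, `n`.
#' @export
profile_series_widths <- function(images, positions, pixel_size = 1,
                                  wavelength = NULL, n = 1.33) {
  if (length(images) < 3) stop("need at least 3 profile positions")
  if (length(positions) != length(images)) {
    stop("positions and images differ in length")
  }
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  sig <- rep(NA_real_, length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    f <- tryCatch(fit_gaussian_2d(img,
                                  x = (seq_len(nrow(img)) - 1) * pixel_size,
                                  y = (seq_len(ncol(img)) - 1) * pixel_size,
                                  fix_theta_zero = TRUE),
                  error = function(e) NULL)
    if (!is.null(f)) sig[i] <- f$sigma_x
  }
  ok <- !is.na(sig)
  structure(list(positions = positions, sigma_x = sig, w = 2 * sig,
                 ok = ok, wavelength = wavelength, n = n),
            class = "beam_profile_series")
}

#' Fit the Gaussian-beam width hyperbola
#'
#' Least-squares fit of `w(x) = w0 sqrt(1 + ((x - x0) / xR)^2)` to the
#' measured beam widths, yielding the waist `w0` (the light-sheet
#' half-thickness), the Rayleigh length `xR` and the waist position `x0`.
#'
#' @param series a `beam_profile_series` (or a list with `positions` and
#'   `w`).
#' @return List of class `beam_waist_fit`: `w0`, `xR`, `x0`, `residual`.
#' @export
fit_beam_waist <- function(series) {
  pos <- series$positions
  w <- series$w
  ok <- is.finite(w)
  pos <- pos[ok]
  w <- w[ok]
  if (length(w) < 3) stop("need at least 3 valid width samples")
  w00 <- min(w)
  x00 <- pos[which.min(w)]
  xr0 <- max(diff(range(pos)) / 4, 1e-6)
  res_fn <- function(p) w - p[1] * sqrt(1 + ((pos - p[3]) / p[2])^2)
  fit <- minpack.lm::nls.lm(par = c(w00, xr0, x00), fn = res_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  p <- fit$par
  if (fit$info == 0 || any(!is.finite(p))) {
    stop("beam-waist fit did not converge (info = ", fit$info, ")")
  }
  structure(list(w0 = abs(p[1]), xR = abs(p[2]), x0 = p[3],
                 residual = sqrt(mean(res_fn(p)^2))),
            class = "beam_waist_fit")
}

#' Rayleigh length of a Gaussian beam
#'
#' `xR = n pi w0^2 / lambda`: the propagation distance over which the beam
#' width grows by sqrt(2).
#'
#' @param w0 beam waist (1/e^2 radius), micrometres.
#' @param wavelength wavelength in micrometres.
#' @param n refractive index of the medium (1.33 for water).
#' @return Rayleigh length in micrometres.
#' @export
rayleigh_length <- function(w0, wavelength, n = 1.33) {
  if (w0 <= 0 || wavelength <= 0 || n <= 0) {
    stop("w0, wavelength and n must be strictly positive")
  }
  n * pi * w0^2 / wavelength
}

# strict 26-neighborhood local maxima of a 3D array above a threshold,
# greedy minimum separation, strongest first
detect_beads <- function(stack, n_max = Inf, min_sep = c(3, 5, 5),
                         rel_thresh = 0.25) {
  dims <- dim(stack)
  bg <- stats::median(stack)
  if (max(stack) <= bg) return(matrix(integer(), 0, 3))
  thr <- bg + rel_thresh * (max(stack) - bg)
  is_max <- array(TRUE, dims)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- seq_len(dims[1]) + dz
    sy <- seq_len(dims[2]) + dy
    sx <- seq_len(dims[3]) + dx
    okz <- sz >= 1 & sz <= dims[1]
    oky <- sy >= 1 & sy <= dims[2]
    okx <- sx >= 1 & sx <= dims[3]
    nbv <- array(-Inf, dims)
    nbv[okz, oky, okx] <- stack[sz[okz], sy[oky], sx[okx]]
    # non-strict: a bead centered between two voxels forms an equal-valued
    # plateau; the min-separation pass keeps one voxel of it
    is_max <- is_max & (stack >= nbv)
  }
  cand <- which(is_max & stack >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(integer(), 0, 3))
  ord <- order(-stack[cand], cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  kept <- matrix(0L, 0, 3)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) >= n_max) break
    if (nrow(kept) > 0) {
      dd <- abs(sweep(kept, 2, cand[i, ]))
      if (any(apply(sweep(dd, 2, min_sep, "<="), 1, all))) next
    }
    kept <- rbind(kept, cand[i, ])
  }
  kept
}

# intensity-weighted sub-voxel centroid around a detected maximum, um
bead_centroid_um <- function(stack, center, meta, win = c(2L, 3L, 3L)) {
  dims <- dim(stack)
  lo <- pmax(1L, center - win)
  hi <- pmin(dims, center + win)
  gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
  sub <- stack[gz, gy, gx, drop = FALSE]
  sub <- pmax(sub - min(sub), 0)
  tot <- sum(sub)
  co <- c(sum(apply(sub, 1, sum) * gz), sum(apply(sub, 2, sum) * gy),
          sum(apply(sub, 3, sum) * gx)) / tot
  (co - 1) * meta$voxel_size
}

#' Measure the point spread function from a bead stack
#'
#' Detects up to `n_beads` well-separated local maxima, extracts the
#' lateral (x, y) and axial (z) intensity line profiles through each bead
#' center — the line profiles drawn in the three central planes (xy, xz,
#' yz); through the center the two lateral x lines (and likewise y and z)
#' coincide on gridded data — fits each with a 1D Gaussian in physical
#' coordinates, and aggregates the 1/e radii `sigma_x,y,z` as mean and
#' standard deviation across beads.
#'
#' @param stack 3D image `(z, y, x)`.
#' @param n_beads maximum number of beads to use.
#' @param meta a [movie_meta()] giving the voxel size.
#' @param window_um half-length of the extracted line profiles around each
#'   bead center, micrometres; keeps neighboring beads out of the fit.
#' @return List of class `psf_measurement`: `per_bead` (data frame with
#'   `sigma_z`, `sigma_y`, `sigma_x` in um), `mean`, `sd`, `n_beads`.
#'   With a single bead the sd is reported as 0.
#' @export
measure_psf <- function(stack, n_beads = 10L, meta = movie_meta(),
                        window_um = 8) {
  stopifnot(inherits(meta, "movie_meta"))
  beads <- detect_beads(stack, n_max = n_beads)
  if (nrow(beads) == 0) stop("no beads detected in the stack")
  vs <- meta$voxel_size
  dims <- dim(stack)
  rows <- lapply(seq_len(nrow(beads)), function(i) {
    b <- beads[i, ]
    line <- function(v, grid, center) {
      ok <- abs(grid - center) <= window_um
      list(v = v[ok], grid = grid[ok])
    }
    prof <- list(
      z = line(stack[, b[2], b[3]], (seq_len(dims[1]) - 1) * vs[1],
               (b[1] - 1) * vs[1]),
      y = line(stack[b[1], , b[3]], (seq_len(dims[2]) - 1) * vs[2],
               (b[2] - 1) * vs[2]),
      x = line(stack[b[1], b[2], ], (seq_len(dims[3]) - 1) * vs[3],
               (b[3] - 1) * vs[3]))
    s <- vapply(prof, function(p) {
      f <- tryCatch(fit_gaussian_1d(p$grid, p$v), error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$sigma
    }, numeric(1))
    data.frame(sigma_z = s[["z"]], sigma_y = s[["y"]], sigma_x = s[["x"]])
  })
  per_bead <- do.call(rbind, rows)
  per_bead <- per_bead[stats::complete.cases(per_bead), , drop = FALSE]
  if (nrow(per_bead) == 0) stop("no bead yielded a full set of profile fits")
  mu <- colMeans(per_bead)
  sdv <- if (nrow(per_bead) > 1) apply(per_bead, 2, stats::sd) else
    stats::setNames(rep(0, 3), names(mu))
  structure(list(per_bead = per_bead, mean = mu, sd = sdv,
                 n_beads = nrow(per_bead)),
            class = "psf_measurement")
}

#' Chromatic shift between two bead stacks
#'
#' Detects beads in both stacks, computes their sub-voxel centroids,
#' matches each bead in `stack_a` to the nearest in `stack_b` within
#' `max_dist`, and reports the mean displacement of `stack_b` relative to
#' `stack_a` in micrometres.
#'
#' @param stack_a,stack_b 3D images of the same bead field in two
#'   channels.
#' @param meta a [movie_meta()].
#' @param max_dist maximum matching distance, micrometres.
#' @return Named numeric `(dz, dy, dx)` in micrometres, with attribute
#'   `n_matched`.
#' @export
chromatic_shift <- function(stack_a, stack_b, meta = movie_meta(),
                            max_dist = 5) {
  ba <- detect_beads(stack_a)
  bb <- detect_beads(stack_b)
  if (nrow(ba) == 0 || nrow(bb) == 0) stop("no beads detected")
  ca <- t(vapply(seq_len(nrow(ba)), function(i)
    bead_centroid_um(stack_a, ba[i, ], meta), numeric(3)))
  cb <- t(vapply(seq_len(nrow(bb)), function(i)
    bead_centroid_um(stack_b, bb[i, ], meta), numeric(3)))
  deltas <- matrix(0, 0, 3)
  for (i in seq_len(nrow(ca))) {
    dd <- sqrt(rowSums(sweep(cb, 2, ca[i, ])^2))
    j <- which.min(dd)
    if (dd[j] <= max_dist) deltas <- rbind(deltas, cb[j, ] - ca[i, ])
  }
  if (nrow(deltas) == 0) stop("no matched beads within ", max_dist, " um")
  out <- colMeans(deltas)
  names(out) <- c("dz", "dy", "dx")
  attr(out, "n_matched") <- nrow(deltas)
  out
}
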