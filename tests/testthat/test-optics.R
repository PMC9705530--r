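gauss1d <- function(x, d, A, x0, s) d + A * exp(-(x - x0)^2 / (2 * s^2))

test_that("1D Gaussian fits recover noiseless parameters exactly", {
  x <- seq(-10, 10, by = 0.5)
  y <- gauss1d(x, 1.5, 10, 2, 2)
  f <- fit_gaussian_1d(x, y)
  expect_equal(f$sigma, 2, tolerance = 1e-6)
  expect_equal(f$x0, 2, tolerance = 1e-6)
  expect_equal(f$A, 10, tolerance = 1e-6)
  expect_equal(f$d, 1.5, tolerance = 1e-6)
  # translation equivariance: shifting x shifts x0, sigma unchanged
  f2 <- fit_gaussian_1d(x + 3, y)
  expect_equal(f2$x0, f$x0 + 3, tolerance = 1e-6)
  expect_equal(f2$sigma, f$sigma, tolerance = 1e-6)
  # constant offset moves d only
  f3 <- fit_gaussian_1d(x, y + 5)
  expect_equal(f3$d, f$d + 5, tolerance = 1e-6)
  expect_equal(f3$sigma, f$sigma, tolerance = 1e-6)
  expect_error(fit_gaussian_1d(x, rep(1, length(x))), "degenerate")
  expect_error(fit_gaussian_1d(1:3, 1:3), "at least 5")
})

test_that("2D Gaussian fits recover widths, symmetry and rotation", {
  x <- seq(0, 30); y <- seq(0, 20)
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  img <- 0.3 + 5 * exp(-((X - 14)^2 / (2 * 3^2) + (Y - 9)^2 / (2 * 1^2)))
  f <- fit_gaussian_2d(img, x, y)
  expect_equal(f$sigma_x, 3, tolerance = 1e-6)
  expect_equal(f$sigma_y, 1, tolerance = 1e-6)
  # a, b, c consistent with the theta = 0 closed forms
  expect_equal(f$a, 1 / (2 * 3^2), tolerance = 1e-6)
  expect_equal(f$b, 0)
  expect_equal(f$c, 1 / (2 * 1^2), tolerance = 1e-6)
  # symmetric input: equal widths
  sym <- exp(-((X - 14)^2 + (Y - 9)^2) / (2 * 2^2))
  fs <- fit_gaussian_2d(sym, x, y)
  expect_equal(fs$sigma_x, fs$sigma_y, tolerance = 1e-6)
  # transposition swaps the axes
  ft <- fit_gaussian_2d(t(img), y, x)
  expect_equal(ft$sigma_x, 1, tolerance = 1e-6)
  expect_equal(ft$sigma_y, 3, tolerance = 1e-6)
  # rotated Gaussian recovered with the free-angle model
  th <- pi / 6
  a <- cos(th)^2 / (2 * 3^2) + sin(th)^2 / (2 * 1.2^2)
  b <- -sin(2 * th) / (4 * 3^2) + sin(2 * th) / (4 * 1.2^2)
  cc <- sin(th)^2 / (2 * 3^2) + cos(th)^2 / (2 * 1.2^2)
  rot <- 2 * exp(-(a * (X - 14)^2 + 2 * b * (X - 14) * (Y - 9) +
                     cc * (Y - 9)^2))
  fr <- fit_gaussian_2d(rot, x, y, fix_theta_zero = FALSE)
  sig <- sort(c(fr$sigma_x, fr$sigma_y))
  expect_equal(sig, c(1.2, 3), tolerance = 1e-4)
})

test_that("beam-width series and hyperbola fit recover the waist", {
  w0 <- 2.7; xR <- 54; x0 <- 10
  positions <- seq(-80, 100, by = 10)
  wx <- w0 * sqrt(1 + ((positions - x0) / xR)^2)
  px <- 0.5
  images <- lapply(wx, function(w) {
    gx <- seq(0, 40) * px; gy <- seq(0, 40) * px
    outer(exp(-(gx - 10)^2 / (2 * (w / 2)^2)),
          exp(-(gy - 10)^2 / (2 * 3^2)))
  })
  ser <- profile_series_widths(images, positions, pixel_size = px)
  expect_true(all(ser$ok))
  expect_equal(ser$w, wx, tolerance = 1e-4)
  fit <- fit_beam_waist(ser)
  expect_equal(fit$w0, w0, tolerance = 1e-4)
  expect_equal(fit$xR, xR, tolerance = 1e-4)
  expect_equal(fit$x0, x0, tolerance = 1e-3)
  # hyperbola identities at the waist and one Rayleigh length out
  w_at <- function(x) fit$w0 * sqrt(1 + ((x - fit$x0) / fit$xR)^2)
  expect_equal(w_at(fit$x0), fit$w0)
  expect_equal(w_at(fit$x0 + fit$xR), fit$w0 * sqrt(2), tolerance = 1e-12)
  # reversing the propagation axis leaves w0 and xR unchanged
  fit_rev <- fit_beam_waist(list(positions = rev(-positions), w = rev(wx)))
  expect_equal(fit_rev$w0, w0, tolerance = 1e-4)
  expect_equal(fit_rev$xR, xR, tolerance = 1e-4)
  expect_error(profile_series_widths(images[1:2], positions[1:2]),
               "at least 3")
  # identical images give a constant width series
  ser2 <- profile_series_widths(images[c(1, 1, 1)], 1:3, pixel_size = px)
  expect_equal(ser2$w[1], ser2$w[2], tolerance = 1e-9)
})

test_that("rayleigh length follows the closed form and its scaling laws", {
  expect_equal(rayleigh_length(2, 0.561, 1.33), 1.33 * pi * 4 / 0.561,
               tolerance = 1e-12)
  expect_equal(rayleigh_length(2, 0.561, 1.33), 29.79, tolerance = 1e-3)
  expect_equal(rayleigh_length(4, 0.561, 1.33),
               4 * rayleigh_length(2, 0.561, 1.33))
  expect_equal(rayleigh_length(2, 0.561, 1.33) / rayleigh_length(2, 0.561, 1),
               1.33)
  expect_error(rayleigh_length(-1, 0.5), "positive")
})

test_that("PSF measurement recovers per-axis bead widths in micrometres", {
  meta <- tiny_meta(24L, voxel = c(0.4, 0.25, 0.25))
  dims <- c(24L, 64L, 64L)
  set.seed(71)
  # beads separated by well over 10 sigma in the lateral plane
  pos <- rbind(c(4.0, 3.2, 3.1), c(5.0, 12.4, 3.4), c(4.4, 3.7, 12.9))
  sig <- c(1.7, 0.9, 0.9)
  stack <- make_bead_stack(sig, pos, meta, dims = dims, noise_sd = 2,
                           seed = 72L)
  psf <- measure_psf(stack, n_beads = 3L, meta = meta)
  expect_equal(psf$n_beads, 3)
  expect_equal(unname(psf$mean[["sigma_z"]]), 1.7, tolerance = 0.05)
  expect_equal(unname(psf$mean[["sigma_y"]]), 0.9, tolerance = 0.05)
  expect_equal(unname(psf$mean[["sigma_x"]]), 0.9, tolerance = 0.05)
  # single bead: n = 1, sd reported as 0
  st1 <- make_bead_stack(sig, pos[1, , drop = FALSE], meta, dims = dims)
  p1 <- measure_psf(st1, n_beads = 1L, meta = meta)
  expect_equal(p1$n_beads, 1)
  expect_true(all(p1$sd == 0))
  expect_error(measure_psf(array(0, dims) + 1, meta = meta), "no beads")
})

test_that("anisotropic voxel sampling converts widths to micrometres", {
  # same physical bead sampled at two voxel geometries gives one answer
  sig <- c(1.6, 0.8, 0.8)
  m1 <- tiny_meta(30L, voxel = c(0.3, 0.2, 0.2))
  m2 <- tiny_meta(18L, voxel = c(0.5, 0.45, 0.3))
  s1 <- make_bead_stack(sig, rbind(c(4, 3, 3)), m1, dims = c(30L, 32L, 32L))
  s2 <- make_bead_stack(sig, rbind(c(4, 3, 3)), m2, dims = c(18L, 15L, 21L))
  p1 <- measure_psf(s1, 1L, m1)
  p2 <- measure_psf(s2, 1L, m2)
  expect_equal(unname(unlist(p1$mean)), unname(unlist(p2$mean)),
               tolerance = 0.05)
  expect_equal(unname(unlist(p1$mean)), sig, tolerance = 0.05)
})

test_that("chromatic shift is the mean displacement of matched beads", {
  meta <- tiny_meta(24L, voxel = c(0.4, 0.25, 0.25))
  dims <- c(24L, 64L, 64L)
  pos <- rbind(c(4.0, 3.2, 3.1), c(5.0, 12.4, 3.4), c(4.4, 3.7, 12.9))
  sig <- c(1.5, 0.8, 0.8)
  a <- make_bead_stack(sig, pos, meta, dims = dims)
  expect_equal(as.numeric(chromatic_shift(a, a, meta)), c(0, 0, 0),
               tolerance = 1e-9)
  b <- make_bead_stack(sig, sweep(pos, 2, c(1, 0, 0), "+"), meta,
                       dims = dims)
  sh <- chromatic_shift(a, b, meta)
  expect_equal(unname(sh[["dz"]]), 1, tolerance = 0.1)
  expect_lt(max(abs(sh[c("dy", "dx")])), 0.1)
  far <- make_bead_stack(sig, sweep(pos, 2, c(0, 2.5, 2.5), "+"), meta,
                         dims = dims)
  expect_error(chromatic_shift(a, far, meta, max_dist = 2), "match")
})
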