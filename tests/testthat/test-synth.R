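test_that("half-life conversion and calibrated kernel agree with the sensor", {
  kin <- sensor_kinetics()
  # per-phase half-life conversion: tau = t_half / ln 2
  kh <- make_kernel(kin, dt = 1e-3, duration = 10, conversion = "halflife")
  expect_equal(attr(kh, "tau_d"), 0.78 / log(2), tolerance = 1e-12)
  expect_equal(attr(kh, "tau_d"), 1.1254, tolerance = 1e-4)
  # calibrated kernel: measured half-times equal the sensor's
  k <- make_kernel(kin, dt = 1e-3, duration = 10)
  ht <- kernel_half_times(k)
  expect_equal(ht$decay, 0.78, tolerance = 2e-3)
  expect_equal(ht$rise, 0.09, tolerance = 2e-3)
  # unit peak, zero at origin, single maximum
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)
  expect_equal(sum(diff(sign(diff(k))) < 0), 1)
})

test_that("kernel construction rejects unphysical parameters", {
  expect_error(sensor_kinetics(t_half_rise = -1), "positive")
  expect_error(sensor_kinetics(0.8, 0.5), "exceed")
  kin <- sensor_kinetics()
  expect_error(make_kernel(kin, dt = 0), "positive")
  expect_error(make_kernel(kin, dt = 1e-3, duration = 1), "half-times")
})

test_that("ground truth is deterministic and morphologically in-range", {
  cfg <- quiet_config(shape = c(20L, 12L, 48L, 48L), n_active = 4L,
                      n_static = 2L,
                      meta = movie_meta(voxel_size = c(3, 1.3, 1.3),
                                        frame_interval = 0.2,
                                        plane_exposure = 0.01,
                                        n_planes = 12L))
  gt1 <- generate_ground_truth(cfg)
  gt2 <- generate_ground_truth(cfg)
  expect_identical(gt1, gt2)
  vv <- voxel_volume(cfg$meta)
  vols <- sapply(gt1$footprints, function(f) length(f$idx)) * vv
  expect_true(all(vols >= 710 & vols <= 7605))
  # voxelized volume consistent with the analytic ellipsoid volume
  analytic <- 4 / 3 * pi * prod(cfg$soma_radii_um)
  expect_true(all(abs(vols - analytic) / analytic < 0.2))
  expect_true(all(gt1$clean_traces >= 0))
  expect_true(all(diff(gt1$bleach_curve) <= 0))
  expect_true(all(gt1$bleach_curve > 0 & gt1$bleach_curve <= 1))
})

test_that("clean traces equal the spike train convolved with the kernel", {
  cfg <- quiet_config(shape = c(60L, 8L, 28L, 28L), n_active = 2L,
                      firing_rate = 0.3)
  gt <- generate_ground_truth(cfg)
  dt <- cfg$meta$frame_interval
  nt <- cfg$shape[1]
  kern <- make_kernel(cfg$kinetics, dt = dt)
  for (i in seq_along(gt$spike_times)) {
    ref <- numeric(nt)
    for (ts in gt$spike_times[[i]]) {
      b <- min(nt, floor(ts / dt) + 1)     # spike binned to its frame
      span <- b:min(nt, b + length(kern) - 1)
      ref[span] <- ref[span] + kern[seq_along(span)]
    }
    expect_equal(gt$clean_traces[i, ], ref, tolerance = 1e-8)
  }
})

test_that("n_active = 0 reduces the movie to background", {
  cfg <- quiet_config(shape = c(6L, 6L, 20L, 20L), n_active = 0L,
                      n_static = 0L)
  gt <- generate_ground_truth(cfg)
  expect_length(gt$footprints, 0)
  mv <- render_movie(gt, cfg)
  # every frame identical: static background only
  for (t in 2:6) expect_equal(mv$data[t, , , ], mv$data[1, , , ])
})

test_that("rendering is deterministic and additive over disjoint neuron sets", {
  cfg <- quiet_config(shape = c(15L, 8L, 32L, 32L), n_active = 3L,
                      n_static = 0L, seed = 3L)
  gt <- generate_ground_truth(cfg)
  expect_identical(render_movie(gt, cfg)$data, render_movie(gt, cfg)$data)
  subset_gt <- function(gt, ids) {
    g <- gt
    g$footprints <- gt$footprints[ids]
    g$clean_traces <- gt$clean_traces[ids, , drop = FALSE]
    g$spike_times <- gt$spike_times[ids]
    g
  }
  m_all <- render_movie(gt, cfg)$data
  m_a <- render_movie(subset_gt(gt, 1), cfg)$data
  m_b <- render_movie(subset_gt(gt, 2:3), cfg)$data
  m_0 <- render_movie(subset_gt(gt, integer()), cfg)$data
  expect_equal(m_all + m_0, m_a + m_b, tolerance = 1e-9)
})

test_that("bleaching drives the per-volume medians down monotonically", {
  cfg <- quiet_config(shape = c(30L, 8L, 28L, 28L), n_active = 1L,
                      bleach_tau = 200)
  gt <- generate_ground_truth(cfg)
  mv <- render_movie(gt, cfg)
  med <- apply(mv$data, 1, median)
  expect_true(all(diff(med) < 0))
  # medians proportional to the bleach curve (background-dominated median)
  expect_equal(med / med[1], gt$bleach_curve / gt$bleach_curve[1],
               tolerance = 1e-6)
})

test_that("stripe shadows are multiplicative and constant beyond the occluder", {
  cfg <- synth_config(shape = c(10L, 8L, 28L, 28L), n_active = 0L,
                      n_static = 0L, n_stripes = 3L, drift_amplitude = 0,
                      shot_noise = FALSE, read_noise_sd = 0, seed = 5L)
  gt <- generate_ground_truth(cfg)
  fld <- stripe_field_at(gt, 1)
  expect_true(all(fld > 0 & fld <= 1))
  # beyond the furthest occluder start the shadow is x-invariant
  x_from <- ceiling(max(gt$stripes$x0))
  for (x in (x_from + 1):dim(fld)[3]) {
    expect_equal(fld[, , x], fld[, , x_from], tolerance = 1e-12)
  }
  # attenuation actually varies over time (jittering amplitude)
  expect_gt(var(gt$stripes$amp[1, ]), 0)
})

test_that("bead stacks hold the stated Gaussians", {
  meta <- tiny_meta(16L, voxel = c(0.5, 0.3, 0.3))
  pos <- rbind(c(4, 6, 4), c(4, 6, 14))
  # empty positions: zero stack
  z <- make_bead_stack(c(1.7, 0.9, 0.9), matrix(numeric(), 0, 3), meta,
                       dims = c(16L, 40L, 60L))
  expect_true(all(z == 0))
  stack <- make_bead_stack(c(1.7, 0.9, 0.9), pos, meta,
                           dims = c(16L, 40L, 60L))
  # two beads: two local maxima at the stated positions
  i1 <- which(stack == max(stack), arr.ind = TRUE)[1, ]
  expect_equal(as.numeric((i1 - 1) * meta$voxel_size), unname(pos[1, ]),
               tolerance = 0.5)
  far <- stack[, , 31:60]
  i2 <- which(far == max(far), arr.ind = TRUE)[1, ]
  expect_equal(unname((i2[3] + 30 - 1) * 0.3), pos[2, 3], tolerance = 0.5)
  expect_error(make_bead_stack(c(1, 1, 1), rbind(c(-5, 0, 0)), meta,
                               dims = c(16L, 40L, 60L)), "outside")
})
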