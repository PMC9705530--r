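# build a movie from planted footprint/trace pairs plus optional baseline
planted_movie <- function(fps, traces, dims, baseline = 0) {
  nt <- ncol(traces)
  arr <- array(baseline, c(nt, dims))
  for (t in seq_len(nt)) {
    vol <- array(baseline, dims)
    for (i in seq_along(fps)) {
      vol[fps[[i]]$idx] <- vol[fps[[i]]$idx] + fps[[i]]$w * traces[i, t]
    }
    arr[t, , , ] <- vol
  }
  tiny_movie(arr)
}

blob_footprint <- function(center, dims, sigma = 1.5, radius = 3L) {
  lo <- pmax(1L, center - radius); hi <- pmin(dims, center + radius)
  idx <- voltrace:::box_indices(lo, hi, dims)
  zyx <- voltrace:::idx_to_zyx(idx, dims)
  d2 <- rowSums(sweep(zyx, 2, as.numeric(center))^2)
  keep <- d2 <= radius^2
  list(idx = idx[keep], w = exp(-d2[keep] / (2 * sigma^2)))
}

test_that("correlation image matches the explicit neighbor-pair oracle", {
  set.seed(31)
  arr <- array(rexp(10 * 4 * 6 * 5), c(10, 4, 6, 5))
  mv <- tiny_movie(arr)
  ci <- correlation_image(mv)
  dims <- dim(arr)[2:4]
  oracle <- array(0, dims)
  for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
    rs <- c()
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      n <- c(z, y, x) + d
      if (any(n < 1) || any(n > dims)) next
      a <- arr[, z, y, x]; b <- arr[, n[1], n[2], n[3]]
      r <- if (sd(a) == 0 || sd(b) == 0) 0 else {
        # population-normalized correlation, as the image uses
        sum(scale(a, scale = FALSE) * scale(b, scale = FALSE)) /
          (sqrt(sum(scale(a, scale = FALSE)^2)) *
           sqrt(sum(scale(b, scale = FALSE)^2)))
      }
      rs <- c(rs, r)
    }
    oracle[z, y, x] <- mean(rs)
  }
  expect_equal(ci, oracle, tolerance = 1e-10)
  # independent noise scores near zero on average
  expect_lt(mean(abs(ci)), 0.2)
  expect_lt(abs(mean(ci)), 0.1)
})

test_that("shared signal saturates the correlation image", {
  set.seed(32)
  tr <- cumsum(rnorm(30))
  arr <- array(0, c(30, 4, 6, 6))
  for (t in 1:30) arr[t, , , ] <- tr[t] - min(tr) + 1 +
    array(rnorm(4 * 6 * 6, 0, 1e-4), c(4, 6, 6))
  ci <- correlation_image(tiny_movie(arr))
  expect_true(all(ci > 0.99))
  # a single flickering voxel in a static surround scores 0 with neighbors
  arr2 <- array(1, c(20, 4, 8, 8))
  arr2[, 2, 4, 4] <- 1 + abs(rnorm(20))
  ci2 <- correlation_image(tiny_movie(arr2))
  expect_equal(ci2[2, 4, 4], 0)   # neighbors are zero-variance
})

test_that("seeding finds separated blobs, respects K, ignores flat maps", {
  dims <- c(6L, 24L, 24L)
  corr <- array(0, dims)
  zyx <- voltrace:::idx_to_zyx(seq_len(prod(dims)), dims)
  g <- function(c0, a) a * exp(-rowSums(sweep(zyx, 2, c0)^2) / (2 * 2^2))
  corr[] <- g(c(3, 7, 7), 1) + g(c(3, 7, 17), 0.8)
  p <- extract_params(gSig = c(2, 2, 2), K = 10L)
  seeds <- seed_components(corr, p)
  expect_equal(nrow(seeds), 2)
  expect_lt(max(abs(seeds[1, ] - c(3, 7, 7))), 1.01)
  expect_lt(max(abs(seeds[2, ] - c(3, 7, 17))), 1.01)
  # K = 1 keeps only the strongest blob
  s1 <- seed_components(corr, extract_params(gSig = c(2, 2, 2), K = 1L,
                                             rf = 50L))
  expect_equal(nrow(s1), 1)
  expect_lt(max(abs(s1[1, ] - c(3, 7, 7))), 1.01)
  # flat map: no seeds
  expect_equal(nrow(seed_components(array(1, dims), p)), 0)
})

test_that("a single noiseless component is recovered essentially exactly", {
  dims <- c(6L, 16L, 16L)
  fp <- blob_footprint(c(3L, 8L, 8L), dims)
  set.seed(33)
  tr <- matrix(pmax(0, rep(c(0, 2, 5, 1, 0), 6) + rnorm(30, 0, 0.1)), 1)
  mv <- planted_movie(list(fp), tr, dims)
  p <- extract_params(nb = 0L, gSig = c(2, 2, 2), n_iter = 100L)
  m <- fit_model(mv, rbind(c(3, 8, 8)), p)
  # reconstruction error and trace fidelity
  Y <- t(matrix(mv$data, 30, prod(dims)))
  recon <- matrix(0, prod(dims), 30)
  recon[m$A[[1]]$idx, ] <- m$A[[1]]$w %o% m$C[1, ]
  expect_lt(sqrt(sum((Y - recon)^2)) / sqrt(sum(Y^2)), 1e-3)
  expect_gt(cor(m$C[1, ], tr[1, ]), 0.999)
  # objective decreases monotonically
  expect_true(all(diff(m$objective) <= 1e-9))
  # nonnegativity
  expect_true(all(m$A[[1]]$w >= 0))
  expect_true(all(m$C >= 0))
  expect_error(fit_model(mv, matrix(0, 0, 3), p), "seed")
  bad <- mv; bad$data[1] <- NA
  expect_error(fit_model(bad, rbind(c(3, 8, 8)), p), "NaN")
})

test_that("the fit matches a direct rank-1 alternating least squares oracle", {
  dims <- c(4L, 12L, 12L)
  fp <- blob_footprint(c(2L, 6L, 6L), dims, radius = 2L)
  tr <- matrix(c(1, 4, 2, 6, 0.5, 3, 5, 2, 1, 4), 1)
  mv <- planted_movie(list(fp), tr, dims)
  m <- fit_model(mv, rbind(c(2, 6, 6)),
                 extract_params(nb = 0L, n_iter = 200L, tol = 1e-12))
  # oracle: unconstrained rank-1 ALS on the full matrix
  Y <- t(matrix(mv$data, ncol(tr), prod(dims)))
  a <- rowMeans(Y)
  for (i in 1:200) {
    cvec <- as.numeric(crossprod(a, Y)) / sum(a^2)
    a <- as.numeric(Y %*% cvec) / sum(cvec^2)
  }
  recon_als <- a %o% cvec
  recon_fit <- matrix(0, prod(dims), ncol(tr))
  recon_fit[m$A[[1]]$idx, ] <- m$A[[1]]$w %o% m$C[1, ]
  expect_lt(sqrt(sum((recon_fit - recon_als)^2)) /
              sqrt(sum(recon_als^2)), 1e-6)
})

test_that("disjoint neurons map one-to-one onto components", {
  dims <- c(6L, 24L, 24L)
  fps <- list(blob_footprint(c(3L, 7L, 7L), dims),
              blob_footprint(c(3L, 16L, 16L), dims))
  set.seed(34)
  tr <- matrix(abs(rnorm(2 * 40)), 2)
  mv <- planted_movie(fps, tr, dims)
  m <- fit_model(mv, rbind(c(3, 7, 7), c(3, 16, 16)),
                 extract_params(nb = 0L, n_iter = 50L))
  cc <- abs(cor(t(m$C), t(tr)))
  expect_gt(min(diag(cc)), 0.99)
  expect_lt(max(cc - diag(diag(cc))), 0.5)
})

test_that("component evaluation applies the stated SNR and rval formulas", {
  dims <- c(6L, 16L, 16L)
  fp <- blob_footprint(c(3L, 8L, 8L), dims)
  nt <- 60L
  tr <- matrix(0, 1, nt)
  tr[1, c(10, 30)] <- 5
  tr[1, c(11, 31)] <- 3
  mv <- planted_movie(list(fp), tr, dims, baseline = 0.1)
  m <- fit_model(mv, rbind(c(3, 8, 8)), extract_params(nb = 0L))
  ev <- evaluate_components(m, mv)
  expect_true(ev$accepted[1])
  expect_gt(ev$spatial_corr[1], 0.95)
  # flat trace: zero peak SNR, rejected
  m2 <- m
  m2$C[1, ] <- 1
  ev2 <- evaluate_components(m2, mv)
  expect_equal(ev2$snr[1], 0)
  expect_false(ev2$accepted[1])
  # pure-noise trace scored by direct formula evaluation
  set.seed(35)
  noise <- rnorm(nt)
  m3 <- m
  m3$C[1, ] <- noise - min(noise)
  ev3 <- evaluate_components(m3, mv)
  tr3 <- m3$C[1, ]
  sig <- 1.4826 * mad(diff(tr3), constant = 1) / sqrt(2)
  expect_equal(ev3$snr[1], (max(tr3) - median(tr3)) / sig, tolerance = 1e-12)
  # empty model: empty flags
  m0 <- m; m0$A <- list(); m0$C <- matrix(0, 0, nt)
  expect_equal(nrow(evaluate_components(m0, mv)), 0)
})

test_that("merging collapses duplicates transitively but respects the threshold", {
  dims <- c(6L, 16L, 16L)
  fp <- blob_footprint(c(3L, 8L, 8L), dims)
  set.seed(36)
  tr <- abs(rnorm(30)) + 0.5
  mk_model <- function(A, C, movie) {
    structure(list(A = A, C = C, b = matrix(0, prod(dims), 0),
                   f = matrix(0, 0, ncol(C)), dims = dims,
                   meta = movie$meta, objective = numeric(0)),
              class = "factor_model")
  }
  mv <- planted_movie(list(fp), matrix(tr, 1), dims)
  # three near-identical overlapping copies merge into one
  m3 <- mk_model(list(fp, fp, fp),
                 rbind(tr, tr * 1.01, tr * 0.99), mv)
  merged <- merge_components(m3, mv)
  expect_length(merged$A, 1)
  expect_gt(cor(merged$C[1, ], tr), 0.999)
  # overlapping but weakly correlated traces stay separate
  set.seed(37)
  tr2 <- abs(rnorm(30))
  while (cor(tr, tr2) > 0.5) tr2 <- abs(rnorm(30))
  m2 <- mk_model(list(fp, fp), rbind(tr, tr2), mv)
  expect_length(merge_components(m2, mv)$A, 2)
  # disjoint footprints never merge, however correlated
  fp_far <- blob_footprint(c(3L, 8L, 14L), dims, radius = 2L)
  expect_length(merge_components(mk_model(list(fp, fp_far),
                                          rbind(tr, tr), mv), mv)$A, 2)
})

test_that("two-pass extraction recovers planted neurons and rejects noise", {
  cfg <- quiet_config(shape = c(60L, 8L, 28L, 28L), n_active = 3L,
                      n_static = 0L, seed = 38L, firing_rate = 0.5,
                      read_noise_sd = 0.5, shot_noise = TRUE)
  sim <- simulate_movie(cfg)
  cs <- run_extraction(sim$movie, extract_params())
  m <- match_and_score_traces(cs, sim$gt)
  expect_gte(nrow(m$matches), 2)
  expect_true(all(m$matches$trace_r > 0.8))
  # merge postcondition: no remaining pair overlaps with correlated traces
  if (length(cs$footprints) >= 2) {
    for (i in seq_along(cs$footprints)[-1]) for (j in seq_len(i - 1)) {
      overlap <- length(intersect(cs$footprints[[i]]$idx,
                                  cs$footprints[[j]]$idx)) > 0
      r <- cor(cs$traces[i, ], cs$traces[j, ])
      expect_false(overlap && r >= 0.8)
    }
  }
  # pure noise movie yields nothing at the default thresholds
  set.seed(39)
  noise <- tiny_movie(array(abs(rnorm(40 * 6 * 16 * 16)), c(40, 6, 16, 16)))
  expect_warning(cs0 <- run_extraction(noise, extract_params()),
                 "empty|no components|no seeds")
  expect_length(cs0$footprints, 0)
})

test_that("the residual identity E = Y - AC - B holds at output", {
  dims <- c(6L, 16L, 16L)
  fps <- list(blob_footprint(c(3L, 8L, 8L), dims))
  set.seed(40)
  tr <- matrix(abs(rnorm(20)), 1)
  mv <- planted_movie(fps, tr, dims, baseline = 0.2)
  m <- fit_model(mv, rbind(c(3, 8, 8)), extract_params(nb = 1L))
  E <- model_residual(m, mv)
  Y <- t(matrix(mv$data, 20, prod(dims)))
  AC <- matrix(0, prod(dims), 20)
  AC[m$A[[1]]$idx, ] <- m$A[[1]]$w %o% m$C[1, ]
  expect_equal(E, Y - AC - m$b %*% m$f, tolerance = 1e-10)
})
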