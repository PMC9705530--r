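#' Calcium-sensor response kinetics
#'
#' Half-times of the action-potential-evoked fluorescence response of the
#' indicator. Defaults are the published R-GECO1.0 values: 0.09 s
#' time-to-half-rise and 0.78 s time-to-half-decay.
#'
#' @param t_half_rise time from stimulus onset until the response first
#'   reaches half of its peak, seconds.
#' @param t_half_decay time from the peak until the response first falls to
#'   half of its peak, seconds. Must exceed `t_half_rise`.
#' @return An object of class `sensor_kinetics`.
#' @export
sensor_kinetics <- function(t_half_rise = 0.09, t_half_decay = 0.78) {
  if (t_half_rise <= 0 || t_half_decay <= 0) {
    stop("sensor half-times must be strictly positive")
  }
  if (t_half_decay <= t_half_rise) {
    stop("t_half_decay must exceed t_half_rise")
  }
  structure(list(t_half_rise = t_half_rise, t_half_decay = t_half_decay),
            class = "sensor_kinetics")
}

kernel_fun <- function(tau_r, tau_d) {
  function(t) (1 - exp(-t / tau_r)) * exp(-t / tau_d)
}

# analytic peak time of (1 - e^{-t/tr}) e^{-t/td}
kernel_peak_time <- function(tau_r, tau_d) {
  -tau_r * log(tau_r / (tau_r + tau_d))
}

# exact (continuous-time) half-rise and peak-to-half-decay of the kernel
kernel_half_times_exact <- function(tau_r, tau_d) {
  k <- kernel_fun(tau_r, tau_d)
  tp <- kernel_peak_time(tau_r, tau_d)
  kp <- k(tp)
  rise <- stats::uniroot(function(t) k(t) - kp / 2, c(1e-12, tp),
                         tol = 1e-12)$root
  upper <- tp
  while (k(upper) > kp / 2) upper <- upper * 2
  th <- stats::uniroot(function(t) k(t) - kp / 2, c(tp, upper),
                       tol = 1e-12)$root
  c(rise = rise, decay = th - tp)
}

# solve for (tau_r, tau_d) whose kernel *exhibits* the stated half-times
calibrate_kernel_taus <- function(kinetics) {
  target <- c(kinetics$t_half_rise, kinetics$t_half_decay)
  obj <- function(p) {
    m <- kernel_half_times_exact(exp(p[1]), exp(p[2]))
    sum((m - target)^2)
  }
  init <- log(c(kinetics$t_half_rise, kinetics$t_half_decay) / log(2))
  o <- stats::optim(init, obj, control = list(reltol = 1e-14, maxit = 2000))
  o <- stats::optim(o$par, obj, control = list(reltol = 1e-14, maxit = 2000))
  list(tau_r = exp(o$par[1]), tau_d = exp(o$par[2]))
}

#' Impulse-response kernel of the calcium indicator
#'
#' Builds the single-event fluorescence kernel
#' `k(t) = norm * (1 - exp(-t/tau_r)) * exp(-t/tau_d)`, normalized to unit
#' peak, with `k(0) = 0` and a single maximum.
#'
#' Two conversions from the sensor's half-times to the exponential time
#' constants are available. `"calibrated"` (default) numerically solves for
#' `(tau_r, tau_d)` such that the kernel's *measured* time-to-half-rise and
#' peak-to-half-decay equal the stated half-times; because the rise factor
#' keeps growing past the peak, this is not the same as converting each phase
#' separately. `"halflife"` applies the per-phase conversion
#' `tau = t_half / ln 2` (so `t_half_decay = 0.78` gives
#' `tau_d = 1.1254 s`); its kernel decays from peak to half in about 0.90 s.
#'
#' @param kinetics a [sensor_kinetics()].
#' @param dt sample spacing, seconds.
#' @param duration kernel length, seconds; must cover at least 5 decay
#'   half-times. Default `8 * t_half_decay`.
#' @param conversion `"calibrated"` or `"halflife"`.
#' @return Numeric vector `k` of `floor(duration/dt) + 1` samples with
#'   attributes `dt`, `tau_r`, `tau_d`.
#' @export
make_kernel <- function(kinetics, dt, duration = 8 * kinetics$t_half_decay,
                        conversion = c("calibrated", "halflife")) {
  stopifnot(inherits(kinetics, "sensor_kinetics"))
  conversion <- match.arg(conversion)
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  if (duration < 5 * kinetics$t_half_decay) {
    stop("duration must cover at least 5 decay half-times")
  }
  taus <- if (conversion == "calibrated") {
    calibrate_kernel_taus(kinetics)
  } else {
    list(tau_r = kinetics$t_half_rise / log(2),
         tau_d = kinetics$t_half_decay / log(2))
  }
  t <- seq(0, duration, by = dt)
  k <- kernel_fun(taus$tau_r, taus$tau_d)(t)
  k <- k / max(k)
  attr(k, "dt") <- dt
  attr(k, "tau_r") <- taus$tau_r
  attr(k, "tau_d") <- taus$tau_d
  k
}

#' Measure half-rise and peak-to-half-decay of a sampled kernel
#'
#' @param k numeric kernel samples on a uniform grid starting at t = 0.
#' @param dt sample spacing in seconds (taken from `attr(k, "dt")` when
#'   absent).
#' @return List with `rise` (time from 0 to half peak), `decay` (time from
#'   the peak until the kernel first falls to half peak) and `peak_time`.
#' @export
kernel_half_times <- function(k, dt = attr(k, "dt")) {
  if (is.null(dt)) stop("dt is required")
  ip <- which.max(k)
  kp <- k[ip]
  rise <- (which(k >= kp / 2)[1] - 1) * dt
  after <- k[-seq_len(ip)]
  ih <- which(after <= kp / 2)[1]
  if (is.na(ih)) stop("kernel does not decay to half peak within its support")
  list(rise = rise, decay = ih * dt, peak_time = (ip - 1) * dt)
}

#' Configuration of the synthetic 4D movie generator
#'
#' Defines the statistical structure of a simulated volumetric recording:
#' sparse active neurons with indicator kinetics, static (non-firing)
#' neurons, out-of-focus fluorescence from the finite light-sheet thickness,
#' multiplicative flickering stripe shadows, photobleaching, rigid drift and
#' sensor noise. All randomness is fixed by `seed`.
#'
#' Defaults emulate a 20x recording: a 64 x 64 x 16 voxel subvolume at
#' (3, 1.3, 1.3) um voxel pitch, 300 volumes at 5 Hz (60 s), 20 active and
#' 10 static neurons with soma semi-axes (4.5, 7, 7) um (ellipsoid volume
#' about 924 um^3, inside the 710-7605 um^3 morphological band),
#' homogeneous Poisson firing at 0.1 Hz per neuron, R-GECO kinetics, an 8 um
#' thick light sheet, 6 occluder shadows with 30% attenuation and 50%
#' temporal jitter, a 200 s bleaching time constant, about one voxel of slow
#' drift, and Poisson shot noise plus Gaussian read noise on a counts scale
#' where transients peak about 60 counts over a 50-count resting level.
#'
#' @param shape integer length-4 `(t, z, y, x)`.
#' @param meta a [movie_meta()]; `n_planes` must equal `shape[2]`.
#' @param n_active,n_static numbers of firing and non-firing neurons.
#' @param soma_radii_um ellipsoid semi-axes `(z, y, x)` in micrometres.
#' @param firing_rate events per second per neuron.
#' @param kinetics a [sensor_kinetics()].
#' @param baseline,amplitude resting brightness of a soma above background
#'   and peak transient amplitude, in counts.
#' @param static_baseline resting brightness of non-firing somata (default
#'   equal to `baseline`; the firing/non-firing brightness ratio is not
#'   constrained by the imaging model).
#' @param bg_offset spatially uniform background level, counts.
#' @param sheet_thickness_um light-sheet thickness `2 w0` controlling the
#'   out-of-focus blur scale.
#' @param oof_strength weight of the blurred (out-of-focus) copy added to
#'   each frame.
#' @param n_stripes,stripe_amplitude,stripe_jitter,stripe_sigma_um,stripe_sigma_z_um
#'   occluder-shadow model: number of occluders, mean attenuation depth,
#'   relative temporal jitter of the attenuation, and the Gaussian widths of
#'   the shadow band across y and z, micrometres.
#' @param bleach_tau photobleaching time constant, seconds.
#' @param shot_noise logical, Poisson noise on expected counts.
#' @param read_noise_sd additive Gaussian read noise, counts.
#' @param drift_amplitude peak rigid drift, voxels (z component is halved).
#' @param seed integer seed fixing all randomness.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(shape = c(300L, 16L, 64L, 64L),
                         meta = movie_meta(voxel_size = c(3, 1.3, 1.3),
                                           frame_interval = 0.2,
                                           plane_exposure = 0.01,
                                           n_planes = shape[2]),
                         n_active = 20L,
                         n_static = 10L,
                         soma_radii_um = c(4.5, 7, 7),
                         firing_rate = 0.1,
                         kinetics = sensor_kinetics(),
                         baseline = 30,
                         amplitude = 60,
                         static_baseline = baseline,
                         bg_offset = 20,
                         sheet_thickness_um = 8,
                         oof_strength = 0.5,
                         n_stripes = 6L,
                         stripe_amplitude = 0.3,
                         stripe_jitter = 0.5,
                         stripe_sigma_um = 4,
                         stripe_sigma_z_um = 6,
                         bleach_tau = 200,
                         shot_noise = TRUE,
                         read_noise_sd = 2,
                         drift_amplitude = 1,
                         seed = 0L) {
  stopifnot(length(shape) == 4, all(shape >= 1))
  if (meta$n_planes != shape[2]) stop("meta$n_planes must equal shape[2]")
  if (n_active < 0 || n_static < 0) stop("neuron counts must be >= 0")
  structure(as.list(environment()), class = "synth_config")
}

# voxelized ellipsoid footprint around a (possibly fractional) center;
# returns linear indices into a (z,y,x) volume and center-weighted weights
ellipsoid_footprint <- function(center, radii_vox, dims) {
  lo <- pmax(1L, floor(center - radii_vox))
  hi <- pmin(dims, ceiling(center + radii_vox))
  gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
  co <- expand.grid(z = gz, y = gy, x = gx)
  d2 <- ((co$z - center[1]) / radii_vox[1])^2 +
        ((co$y - center[2]) / radii_vox[2])^2 +
        ((co$x - center[3]) / radii_vox[3])^2
  keep <- d2 <= 1
  idx <- (co$x[keep] - 1L) * dims[1] * dims[2] + (co$y[keep] - 1L) * dims[1] +
    co$z[keep]
  list(idx = as.integer(idx), w = 1 - 0.5 * d2[keep], center = center)
}

place_centers <- function(n, radii_vox, dims, min_sep = 2, cap = 2000L) {
  centers <- matrix(0, 0, 3)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > cap * max(1L, n)) {
      stop("could not place ", n, " somata without overlap (capacity error)")
    }
    c0 <- c(stats::runif(1, radii_vox[1] + 1, dims[1] - radii_vox[1]),
            stats::runif(1, radii_vox[2] + 1, dims[2] - radii_vox[2]),
            stats::runif(1, radii_vox[3] + 1, dims[3] - radii_vox[3]))
    if (nrow(centers) > 0) {
      d <- sweep(centers, 2, c0)
      d <- sweep(d, 2, radii_vox, "/")
      if (min(sqrt(rowSums(d^2))) < min_sep) next
    }
    centers <- rbind(centers, c0)
  }
  centers
}

smooth_ar1 <- function(n, rho = 0.9) {
  e <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- e[1]
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + sqrt(1 - rho^2) * e[i]
  x
}

#' Generate ground truth for a synthetic recording
#'
#' Places non-overlapping ellipsoidal somata, draws homogeneous Poisson spike
#' trains, convolves them with the indicator kernel into clean traces, and
#' draws the nuisance processes (photobleaching curve, stripe-occluder field
#' parameters with temporal jitter, rigid drift). Deterministic under
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return A list of class `ground_truth` with elements `footprints` (per
#'   active neuron: voxel indices `idx`, weights `w`, `center` in voxels),
#'   `spike_times` (seconds), `clean_traces` (`n_active x t` matrix, unit
#'   peak-kernel scale), `static_footprints`, `static_mask` (3D array),
#'   `bleach_curve`, `stripes` (occluder parameters and per-volume
#'   amplitudes), `drift` (`t x 3` voxel shifts), `dims`, `config`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  dims <- config$shape[2:4]
  nt <- config$shape[1]
  dt <- config$meta$frame_interval
  radii_vox <- config$soma_radii_um / config$meta$voxel_size
  n_all <- config$n_active + config$n_static
  centers <- if (n_all > 0) place_centers(n_all, radii_vox, dims) else
    matrix(0, 0, 3)
  fps <- lapply(seq_len(config$n_active), function(i)
    ellipsoid_footprint(centers[i, ], radii_vox, dims))
  sfps <- lapply(seq_len(config$n_static), function(i)
    ellipsoid_footprint(centers[config$n_active + i, ], radii_vox, dims))
  static_mask <- array(0, dims)
  for (f in sfps) static_mask[f$idx] <- static_mask[f$idx] + f$w

  dur <- nt * dt
  kern <- make_kernel(config$kinetics, dt = dt)
  spike_times <- lapply(seq_len(config$n_active), function(i) {
    n <- stats::rpois(1, config$firing_rate * dur)
    sort(stats::runif(n, 0, dur))
  })
  traces <- matrix(0, max(config$n_active, 1), nt)
  for (i in seq_len(config$n_active)) {
    s <- numeric(nt)
    bins <- pmin(nt, floor(spike_times[[i]] / dt) + 1L)
    for (b in bins) s[b] <- s[b] + 1
    full <- stats::convolve(c(s, numeric(length(kern))), rev(kern),
                            type = "open")
    traces[i, ] <- pmax(0, full[seq_len(nt)])
  }
  if (config$n_active == 0) traces <- matrix(0, 0, nt)

  bleach <- exp(-(seq_len(nt) - 1) * dt / config$bleach_tau)

  ns <- config$n_stripes
  stripes <- list(
    y0 = stats::runif(ns, 1, dims[2]),
    z0 = stats::runif(ns, 1, dims[1]),
    x0 = stats::runif(ns, 1, dims[3] / 2),
    sigma_y = config$stripe_sigma_um / config$meta$voxel_size[2],
    sigma_z = config$stripe_sigma_z_um / config$meta$voxel_size[1],
    amp = matrix(0, max(ns, 1), nt)
  )
  for (k in seq_len(ns)) {
    jit <- smooth_ar1(nt)
    stripes$amp[k, ] <- pmin(0.95, pmax(0,
      config$stripe_amplitude * (1 + config$stripe_jitter * jit)))
  }
  if (ns == 0) stripes$amp <- matrix(0, 0, nt)

  drift <- matrix(0, nt, 3)
  if (config$drift_amplitude > 0 && nt > 1) {
    for (ax in 1:3) {
      w <- cumsum(stats::rnorm(nt))
      w <- stats::filter(w, rep(1 / 15, 15), sides = 2)
      w[is.na(w)] <- 0
      m <- max(abs(w))
      amp <- config$drift_amplitude * if (ax == 1) 0.5 else 1
      drift[, ax] <- if (m > 0) w / m * amp else 0
    }
  }

  structure(list(footprints = fps, static_footprints = sfps,
                 static_mask = static_mask, spike_times = spike_times,
                 clean_traces = traces, bleach_curve = bleach,
                 stripes = stripes, drift = drift, dims = dims,
                 config = config),
            class = "ground_truth")
}

#' Multiplicative stripe-attenuation field at one time point
#'
#' Each occluder at `(y0, z0)` casts a Gaussian-profile shadow band that
#' starts at its position `x0` and propagates along +x (constant along the
#' illumination axis beyond the occluder), with a per-volume attenuation
#' amplitude.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param t volume index (1-based).
#' @return 3D array `(z, y, x)` of multiplicative factors in `(0, 1]`.
#' @export
stripe_field_at <- function(gt, t) {
  dims <- gt$dims
  field <- array(1, dims)
  st <- gt$stripes
  n <- nrow(st$amp)
  if (n == 0) return(field)
  for (k in seq_len(n)) {
    gz <- exp(-(seq_len(dims[1]) - st$z0[k])^2 / (2 * st$sigma_z^2))
    gy <- exp(-(seq_len(dims[2]) - st$y0[k])^2 / (2 * st$sigma_y^2))
    gx <- as.numeric(seq_len(dims[3]) >= st$x0[k])
    att <- st$amp[k, t] * outer(outer(gz, gy), gx)
    field <- field * (1 - att)
  }
  field
}

#' Render a synthetic 4D movie from ground truth
#'
#' Assembles each volume as
#' `bleach(t) * stripe(t) * shift(drift(t), cells + oof * blur(cells)) + noise`
#' where `cells` is the sum of active footprints times
#' `baseline + amplitude * trace(t)`, static somata at their baseline, and a
#' uniform background offset; `blur` is a 3D Gaussian whose axial scale is
#' set by the light-sheet thickness (out-of-focus fluorescence). Noise is
#' Poisson shot noise on the expected counts plus Gaussian read noise,
#' clipped at zero. Deterministic under `config$seed`.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param config the [synth_config()] used to generate `gt`.
#' @return A [movie4d()].
#' @export
render_movie <- function(gt, config = gt$config) {
  stopifnot(inherits(gt, "ground_truth"), inherits(config, "synth_config"))
  if (!identical(as.integer(gt$dims), as.integer(config$shape[2:4]))) {
    stop("ground-truth dims do not match config shape")
  }
  set.seed(config$seed + 1L)
  dims <- gt$dims
  nt <- config$shape[1]
  nv <- prod(dims)
  vs <- config$meta$voxel_size
  blur_sigma <- c((config$sheet_thickness_um / 2) / vs[1], 1, 1)

  base <- array(config$bg_offset, dims)
  base <- base + config$static_baseline * gt$static_mask
  for (f in gt$footprints) base[f$idx] <- base[f$idx] + config$baseline * f$w

  n_act <- length(gt$footprints)
  basis <- matrix(0, nv, n_act + 1L)
  basis[, 1] <- as.numeric(base + config$oof_strength *
                             gauss_smooth3(base, blur_sigma))
  for (i in seq_len(n_act)) {
    fp <- array(0, dims)
    fp[gt$footprints[[i]]$idx] <- gt$footprints[[i]]$w
    basis[, i + 1L] <- as.numeric(fp + config$oof_strength *
                                    gauss_smooth3(fp, blur_sigma))
  }
  coef <- rbind(rep(1, nt),
                if (n_act > 0) config$amplitude * gt$clean_traces else NULL)
  clean <- basis %*% coef  # nv x nt expected counts before nuisances

  out <- array(0, c(nt, dims))
  for (t in seq_len(nt)) {
    vol <- array(clean[, t], dims)
    if (any(gt$drift[t, ] != 0)) {
      vol <- shift_volume(vol, gt$drift[t, ], fill = config$bg_offset)
    }
    lam <- gt$bleach_curve[t] * stripe_field_at(gt, t) * vol
    frame <- if (config$shot_noise) {
      array(stats::rpois(nv, as.numeric(lam)), dims)
    } else lam
    if (config$read_noise_sd > 0) {
      frame <- frame + array(stats::rnorm(nv, 0, config$read_noise_sd), dims)
    }
    out[t, , , ] <- pmax(frame, 0)
  }
  movie4d(out, config$meta)
}

#' Simulate a full synthetic recording
#'
#' Convenience wrapper: ground truth plus rendered movie, optionally written
#' to disk (movie as TIFF hyperstack via [write_hyperstack()], ground-truth
#' spike table as CSV, config echo as JSON).
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory.
#' @return List with `gt` and `movie`.
#' @export
simulate_movie <- function(config = synth_config(), out_dir = NULL) {
  gt <- generate_ground_truth(config)
  movie <- render_movie(gt, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_hyperstack(movie, file.path(out_dir, "movie.tif"))
    spikes <- do.call(rbind, lapply(seq_along(gt$spike_times), function(i) {
      if (length(gt$spike_times[[i]]) == 0) return(NULL)
      data.frame(neuron = i, time_s = gt$spike_times[[i]])
    }))
    if (is.null(spikes)) spikes <- data.frame(neuron = integer(),
                                              time_s = numeric())
    utils::write.csv(spikes, file.path(out_dir, "spikes.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$meta <- meta_to_list(cfg$meta)
    cfg$kinetics <- unclass(cfg$kinetics)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(gt = gt, movie = movie)
}

#' Synthetic bead z-stack for PSF characterization
#'
#' Sum of 3D Gaussians of width `sigma` at stated physical positions
#' (sub-voxel placement) plus optional Gaussian noise. Emulates imaging
#' sub-resolution fluorescent beads in gel.
#'
#' @param sigma `(sz, sy, sx)` Gaussian widths in micrometres.
#' @param positions matrix `n x 3` of physical bead positions `(z, y, x)` in
#'   micrometres; may be empty.
#' @param meta a [movie_meta()] supplying the voxel size.
#' @param dims stack dimensions `(z, y, x)` in voxels.
#' @param amplitude peak intensity per bead.
#' @param noise_sd Gaussian noise level (0 for noiseless).
#' @param seed RNG seed for the noise.
#' @return 3D array `(z, y, x)`.
#' @export
make_bead_stack <- function(sigma, positions, meta,
                            dims = c(16L, 64L, 64L),
                            amplitude = 1000, noise_sd = 0, seed = 0L) {
  stopifnot(inherits(meta, "movie_meta"), length(sigma) == 3)
  positions <- matrix(positions, ncol = 3)
  stack <- array(0, dims)
  vs <- meta$voxel_size
  zg <- (seq_len(dims[1]) - 1) * vs[1]
  yg <- (seq_len(dims[2]) - 1) * vs[2]
  xg <- (seq_len(dims[3]) - 1) * vs[3]
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    if (p[1] < 0 || p[1] > max(zg) || p[2] < 0 || p[2] > max(yg) ||
        p[3] < 0 || p[3] > max(xg)) {
      stop("bead position outside the stack volume")
    }
    bz <- exp(-(zg - p[1])^2 / (2 * sigma[1]^2))
    by <- exp(-(yg - p[2])^2 / (2 * sigma[2]^2))
    bx <- exp(-(xg - p[3])^2 / (2 * sigma[3]^2))
    stack <- stack + amplitude * outer(outer(bz, by), bx)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    stack <- pmax(stack + array(stats::rnorm(prod(dims), 0, noise_sd), dims), 0)
  }
  stack
}

#' Stripe-attributable energy of a movie
#'
#' Projects each temporally centered frame onto the (centered, unit-norm)
#' ground-truth stripe-attenuation pattern of that volume and sums the
#' squared projections. Used to quantify how much stripe contamination a
#' filter removes.
#'
#' @param movie a [movie4d()].
#' @param gt the [generate_ground_truth()] the movie was rendered from.
#' @return Scalar energy (squared intensity units).
#' @export
stripe_energy <- function(movie, gt) {
  stopifnot(inherits(movie, "movie4d"), inherits(gt, "ground_truth"))
  nt <- dim(movie$data)[1]
  mean_frame <- apply(movie$data, 2:4, mean)
  e <- 0
  for (t in seq_len(nt)) {
    s <- stripe_field_at(gt, t) - 1
    s <- s - mean(s)
    ns <- sqrt(sum(s^2))
    if (ns == 0) next
    f <- movie$data[t, , , ] - mean_frame
    e <- e + (sum(f * s) / ns)^2
  }
  e
}
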