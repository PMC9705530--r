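# Shared fixtures: small seeded synthetic configurations and cached
# expensive simulations (built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small, quiet (nuisance-free) configuration for fast construction tests;
# any field can still be overridden through ...
quiet_config <- function(shape = c(40L, 8L, 28L, 28L), n_active = 2L,
                         n_static = 1L, seed = 1L, ...) {
  args <- list(shape = shape, n_active = n_active, n_static = n_static,
               n_stripes = 0L, stripe_amplitude = 0, drift_amplitude = 0,
               oof_strength = 0, shot_noise = FALSE, read_noise_sd = 0,
               bleach_tau = 1e9, seed = seed,
               # somata slightly smaller than the package default so that a
               # handful still pack into the small test volumes (797 um^3,
               # inside the morphological band)
               soma_radii_um = c(4.5, 6.5, 6.5))
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}

# small movie with all nuisances on
noisy_config <- function(shape = c(40L, 8L, 28L, 28L), n_active = 2L,
                         n_static = 1L, seed = 1L, ...) {
  synth_config(shape = shape, n_active = n_active, n_static = n_static,
               seed = seed, ...)
}

# default-condition simulation shared by the acceptance suite
default_sim <- function() {
  cached("default_sim", simulate_movie(synth_config(seed = 0L)))
}

tiny_meta <- function(nz, voxel = c(1, 1, 1)) {
  movie_meta(voxel_size = voxel, frame_interval = 1, plane_exposure = 1e-4,
             n_planes = nz)
}

# movie4d from an array with unit-ish metadata
tiny_movie <- function(arr, voxel = c(1, 1, 1)) {
  movie4d(arr, tiny_meta(dim(arr)[2], voxel))
}

# exact (circular) sub-voxel translation via a spectral phase ramp; the
# smooth periodic construction for motion-recovery fixtures
fourier_shift3 <- function(vol, s) {
  d <- dim(vol)
  ph <- lapply(1:3, function(ax) {
    k <- c(0:(d[ax] %/% 2), -((ceiling(d[ax] / 2) - 1):1))
    exp(-2i * pi * k * s[ax] / d[ax])
  })
  F <- stats::fft(vol) * outer(outer(ph[[1]], ph[[2]]), ph[[3]])
  Re(stats::fft(F, inverse = TRUE)) / prod(d)
}

# component_set with single-voxel or block footprints at given voxel centers
fake_component_set <- function(n_vox_list, traces, dims = c(8L, 20L, 20L),
                               voxel = c(3, 1.3, 1.3)) {
  meta <- tiny_meta(dims[1], voxel)
  fps <- lapply(seq_along(n_vox_list), function(i) {
    idx <- seq_len(n_vox_list[[i]]) + (i - 1L) * max(unlist(n_vox_list))
    list(idx = as.integer(idx), w = rep(1, length(idx)))
  })
  component_set(fps, traces, traces, meta, dims)
}
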