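#' Acquisition metadata for a volumetric movie
#'
#' Bundles the physical geometry and timing of a 4D acquisition: voxel size,
#' volume rate, per-plane exposure and the number of planes per volume.
#'
#' @param voxel_size numeric length-3, voxel pitch `(dz, dy, dx)` in
#'   micrometres. Default `(3, 1.3, 1.3)`: 3 um plane spacing with 1.3 um
#'   lateral pitch (666 um field binned to 512 px on a 20x objective).
#' @param frame_interval seconds between consecutive volumes. Default 0.2 s
#'   (5 volumes per second).
#' @param plane_exposure seconds of camera exposure per plane. Default 0.01 s.
#' @param n_planes planes per volume. Default 20.
#' @param wavelength optional illumination wavelength in nm.
#' @param bidirectional logical, whether the z-scan alternates direction
#'   between consecutive volumes.
#'
#' @return An object of class `movie_meta`.
#' @details `frame_interval` must be at least `n_planes * plane_exposure`:
#'   a volume cannot be scanned faster than its planes are exposed.
#' @seealso [volumetric_rate()], [movie4d()]
#' @export
movie_meta <- function(voxel_size = c(3, 1.3, 1.3),
                       frame_interval = 0.2,
                       plane_exposure = 0.01,
                       n_planes = 20L,
                       wavelength = NULL,
                       bidirectional = FALSE) {
  stopifnot(length(voxel_size) == 3)
  if (any(voxel_size <= 0) || frame_interval <= 0 || plane_exposure <= 0 ||
      n_planes <= 0) {
    stop("all physical quantities in movie_meta must be strictly positive")
  }
  if (frame_interval < n_planes * plane_exposure - 1e-12) {
    stop("frame_interval (", frame_interval, " s) is shorter than n_planes * ",
         "plane_exposure (", n_planes * plane_exposure, " s)")
  }
  structure(list(
    voxel_size = as.numeric(voxel_size),
    frame_interval = as.numeric(frame_interval),
    plane_exposure = as.numeric(plane_exposure),
    n_planes = as.integer(n_planes),
    wavelength = if (is.null(wavelength)) NULL else as.numeric(wavelength),
    bidirectional = isTRUE(bidirectional)
  ), class = "movie_meta")
}

#' Acquisition arithmetic helpers
#'
#' Small derived quantities of the acquisition geometry: the volumetric rate
#' in Hz, the axial extent of a volume in micrometres, and the lateral voxel
#' size implied by a field of view and a pixel count.
#'
#' @param meta a [movie_meta()].
#' @return `volumetric_rate`: volumes per second (`1 / frame_interval`).
#' @export
volumetric_rate <- function(meta) {
  stopifnot(inherits(meta, "movie_meta"))
  1 / meta$frame_interval
}

#' @rdname volumetric_rate
#' @return `axial_extent`: `n_planes * dz` in micrometres.
#' @export
axial_extent <- function(meta) {
  stopifnot(inherits(meta, "movie_meta"))
  meta$n_planes * meta$voxel_size[1]
}

#' @rdname volumetric_rate
#' @param fov_um lateral field of view in micrometres.
#' @param n_px pixel count across that field (after binning).
#' @return `lateral_voxel_size`: `fov_um / n_px` in micrometres.
#' @export
lateral_voxel_size <- function(fov_um, n_px) {
  stopifnot(fov_um > 0, n_px > 0)
  fov_um / n_px
}

#' Volume of one voxel in cubic micrometres
#' @param meta a [movie_meta()].
#' @return `dz * dy * dx` in um^3.
#' @export
voxel_volume <- function(meta) {
  stopifnot(inherits(meta, "movie_meta"))
  prod(meta$voxel_size)
}

#' 4D fluorescence movie
#'
#' A nonnegative intensity array indexed `(t, z, y, x)` together with its
#' acquisition metadata. This is the container every pipeline stage consumes
#' and produces.
#'
#' @param data 4D numeric array with dimensions `(t, z, y, x)`, all values
#'   nonnegative.
#' @param meta a [movie_meta()]; its `n_planes` must match `dim(data)[2]`.
#' @return An object of class `movie4d` with elements `data` and `meta`.
#' @export
movie4d <- function(data, meta) {
  stopifnot(inherits(meta, "movie_meta"))
  if (length(dim(data)) != 4) stop("movie data must have 4 axes (t, z, y, x)")
  if (any(data < 0)) stop("movie intensities must be nonnegative")
  if (dim(data)[2] != meta$n_planes) {
    stop("dim(data)[2] = ", dim(data)[2], " does not match meta$n_planes = ",
         meta$n_planes)
  }
  structure(list(data = data, meta = meta), class = "movie4d")
}

# internal constructor for derived movies (e.g. Fourier-filtered or
# interpolated data, which may legitimately carry small negative values)
new_movie4d <- function(data, meta) {
  structure(list(data = data, meta = meta), class = "movie4d")
}

#' @export
dim.movie4d <- function(x) dim(x$data)

#' @export
print.movie4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie4d> %d volumes of %d x %d x %d (z,y,x) voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um, %.3g volumes/s\n",
              x$meta$voxel_size[1], x$meta$voxel_size[2], x$meta$voxel_size[3],
              1 / x$meta$frame_interval))
  invisible(x)
}

meta_to_list <- function(meta) {
  l <- unclass(meta)
  l[!vapply(l, is.null, logical(1))]
}

meta_from_list <- function(l) {
  movie_meta(voxel_size = l$voxel_size,
             frame_interval = l$frame_interval,
             plane_exposure = l$plane_exposure,
             n_planes = l$n_planes,
             wavelength = l$wavelength,
             bidirectional = isTRUE(l$bidirectional))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a 4D movie as a multi-page TIFF hyperstack
#'
#' Pages are written in t-major, z-minor order (all planes of volume 1, then
#' volume 2, ...). Because TIFF samples are stored in `[0, 1]`, intensities
#' are divided by a scale factor recorded in a JSON sidecar (`<path>.json`)
#' alongside the acquisition metadata: 65535 for integer data (16-bit
#' storage, bit-exact round trip) or the data maximum for float data (32-bit
#' storage, round trip within float precision).
#'
#' @param movie a [movie4d()].
#' @param path output TIFF path; the metadata sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_hyperstack()]
#' @export
write_hyperstack <- function(movie, path) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  is_int <- is.integer(movie$data) ||
    (max(movie$data) <= 65535 && all(movie$data == round(movie$data)))
  scale <- if (is_int) 65535 else max(movie$data, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      pages[[k]] <- movie$data[t, z, , ] / scale
      k <- k + 1L
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (is_int) 16L else 32L),
    error = function(e) stop("cannot write TIFF to '", path, "': ",
                             conditionMessage(e))
  )
  side <- c(meta_to_list(movie$meta),
            list(scale = scale, integer_data = is_int,
                 shape = as.integer(d)))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF hyperstack as a 4D movie
#'
#' Expects pages in t-major, z-minor order. If `meta` is `NULL` the JSON
#' sidecar written by [write_hyperstack()] is consulted; intensities are
#' rescaled by the recorded scale factor so integer data round-trip
#' bit-exactly.
#'
#' @param path a multi-page TIFF file.
#' @param meta a [movie_meta()] describing the acquisition; `NULL` to read it
#'   from the sidecar.
#' @return A [movie4d()].
#' @export
read_hyperstack <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  scale <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    scale <- side$scale
    if (isTRUE(side$integer_data)) scale <- 65535
    if (is.null(meta)) meta <- meta_from_list(side)
  }
  if (is.null(meta)) stop("no metadata: pass `meta` or provide a sidecar")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("'", path,
                                             "' is not a readable TIFF: ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  nz <- meta$n_planes
  if (np %% nz != 0) {
    stop("page count ", np, " is not divisible by n_planes = ", nz)
  }
  nt <- np %/% nz
  dimyx <- dim(pages[[1]])[1:2]
  arr <- array(0, dim = c(nt, nz, dimyx[1], dimyx[2]))
  sc <- if (is.null(scale)) 1 else scale
  k <- 1L
  for (t in seq_len(nt)) {
    for (z in seq_len(nz)) {
      pg <- pages[[k]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]  # drop extra channels
      arr[t, z, , ] <- pg * sc
      k <- k + 1L
    }
  }
  if (!is.null(scale) && sc == 65535) arr <- round(arr)
  movie4d(arr, meta)
}

#' Undo bidirectional z-scan ordering
#'
#' Bidirectional scanning acquires consecutive volumes with alternating
#' z-direction; this reverses the plane order of every odd-indexed volume
#' (or even-indexed, per `reverse_odd`) so that all volumes share one z
#' orientation. Applying the operation twice with the same flag is the
#' identity.
#'
#' @param movie a [movie4d()].
#' @param reverse_odd if `TRUE` (default) volumes 2, 4, ... (1-based odd
#'   zero-based indices) are reversed; if `FALSE`, volumes 1, 3, ....
#'   The acquisition convention is hardware-dependent, hence the flag.
#' @return A [movie4d()] with a consistent z orientation.
#' @export
reorder_bidirectional <- function(movie, reverse_odd = TRUE) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  out <- movie$data
  # zero-based volume indices; parity selects which set is flipped
  idx <- seq_len(d[1])
  flip <- if (reverse_odd) idx[(idx - 1) %% 2 == 1] else idx[(idx - 1) %% 2 == 0]
  for (t in flip) out[t, , , ] <- out[t, d[2]:1, , ]
  movie4d(out, movie$meta)
}
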