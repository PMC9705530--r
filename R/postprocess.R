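#' Set of extracted neuronal components
#'
#' Container for accepted components: weighted 3D footprints, denoised
#' traces, raw (footprint-averaged) traces, centroids in micrometres and
#' voxel counts, plus the shared acquisition metadata.
#'
#' @param footprints list of footprints, each `list(idx, w)` with linear
#'   voxel indices into the `(z, y, x)` volume and positive weights.
#' @param traces `K x T` matrix of denoised traces.
#' @param raw_traces `K x T` matrix of raw traces.
#' @param meta a [movie_meta()].
#' @param dims volume dimensions `(z, y, x)`.
#' @param evaluation optional data frame of per-component quality scores.
#' @return An object of class `component_set`.
#' @export
component_set <- function(footprints, traces, raw_traces, meta, dims,
                          evaluation = NULL) {
  stopifnot(inherits(meta, "movie_meta"))
  K <- length(footprints)
  traces <- matrix(traces, nrow = K)
  raw_traces <- matrix(raw_traces, nrow = K)
  vs <- meta$voxel_size
  centroids <- matrix(0, K, 3, dimnames = list(NULL, c("z", "y", "x")))
  voxels <- integer(K)
  for (i in seq_len(K)) {
    f <- footprints[[i]]
    zyx <- idx_to_zyx(f$idx, dims)
    # physical position of voxel (z,y,x) is its 0-based index times the pitch
    centroids[i, ] <- (colSums(zyx * f$w) / sum(f$w) - 1) * vs
    voxels[i] <- length(f$idx)
  }
  structure(list(footprints = footprints, traces = traces,
                 raw_traces = raw_traces, centroids = centroids,
                 voxel_count = voxels, meta = meta, dims = dims,
                 evaluation = evaluation),
            class = "component_set")
}

#' @export
length.component_set <- function(x) length(x$footprints)

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d time points\n",
              length(x$footprints), ncol(x$traces)))
  invisible(x)
}

#' Subset a component set
#' @param set a [component_set()].
#' @param keep integer or logical index of components to keep.
#' @return A [component_set()] with the selected components.
#' @export
subset_components <- function(set, keep) {
  stopifnot(inherits(set, "component_set"))
  keep <- if (is.logical(keep)) which(keep) else as.integer(keep)
  component_set(set$footprints[keep],
                set$traces[keep, , drop = FALSE],
                set$raw_traces[keep, , drop = FALSE],
                set$meta, set$dims,
                evaluation = if (!is.null(set$evaluation))
                  set$evaluation[keep, , drop = FALSE] else NULL)
}

#' Filter components by physical volume
#'
#' Keeps components whose physical volume, voxel count times voxel volume,
#' lies inside `[vmin, vmax]` (inclusive). The defaults 710 and 7605 um^3
#' bracket typical somata; at the 20x voxel geometry (3 x 1.3 x 1.3 =
#' 5.07 um^3 per voxel) they correspond to 141 and exactly 1500 voxels.
#' Bound comparison carries a 1e-9 relative epsilon so decimally exact
#' volumes (1500 voxels = 7605 um^3) are not lost to float rounding.
#'
#' @param set a [component_set()] with metadata.
#' @param vmin,vmax volume bounds in cubic micrometres.
#' @return The filtered [component_set()], with a `volume_report` attribute
#'   (id, volume, kept).
#' @export
volume_filter <- function(set, vmin = 710, vmax = 7605) {
  stopifnot(inherits(set, "component_set"))
  if (is.null(set$meta)) stop("component set has no metadata (voxel volume unknown)")
  vv <- voxel_volume(set$meta)
  vol <- set$voxel_count * vv
  eps <- 1e-9 * max(vmax, 1)
  keep <- vol >= vmin - eps & vol <= vmax + eps
  out <- subset_components(set, keep)
  attr(out, "volume_report") <- data.frame(id = seq_along(vol),
                                           volume_um3 = vol, kept = keep)
  out
}

#' Normalize a fluorescence trace (delta F over F)
#'
#' Two conventions: `"minmax"`, `(F - Fmin) / (Fmax - Fmin)`, mapping the
#' trace onto `[0, 1]` (amplitude information is lost); and `"baseline"`,
#' `(F - Fmin) / Fmin`, which keeps the trace proportional to the relative
#' change over baseline (minimum 0, unbounded above).
#'
#' @param trace numeric time series.
#' @param mode `"minmax"` or `"baseline"`.
#' @return The normalized trace.
#' @export
normalize_trace <- function(trace, mode = c("minmax", "baseline")) {
  mode <- match.arg(mode)
  fmin <- min(trace)
  fmax <- max(trace)
  if (mode == "minmax") {
    if (fmax <= fmin) stop("degenerate trace: Fmax must exceed Fmin for minmax")
    (trace - fmin) / (fmax - fmin)
  } else {
    if (fmin <= 0) stop("degenerate trace: Fmin must be positive for baseline")
    (trace - fmin) / fmin
  }
}

#' Filter components by normalized trace variance
#'
#' Each denoised trace is min-max normalized to `[0, 1]` and its temporal
#' variance computed. Components whose variance exceeds `threshold` are
#' discarded: after normalization a slow background drift spans the whole
#' interval and has variance near 1/12 (about 0.083), while a sparse
#' transient trace with active fraction `p` has variance about `p (1 - p)`,
#' well below the default 0.06 — so the threshold separates
#' drift-dominated false positives (removed) from genuine sparse activity
#' (kept). Set `discard_high = FALSE` to flip the direction. Constant
#' traces are discarded as degenerate.
#'
#' @param set a [component_set()].
#' @param threshold variance threshold on the normalized trace.
#' @param discard_high discard components above (`TRUE`, default) or below
#'   the threshold.
#' @return The filtered [component_set()] with a `variance_report`
#'   attribute (id, variance, kept, reason).
#' @export
variance_filter <- function(set, threshold = 0.06, discard_high = TRUE) {
  stopifnot(inherits(set, "component_set"))
  K <- length(set$footprints)
  v <- rep(NA_real_, K)
  reason <- character(K)
  keep <- logical(K)
  for (i in seq_len(K)) {
    tr <- set$traces[i, ]
    if (max(tr) <= min(tr)) {
      keep[i] <- FALSE
      reason[i] <- "degenerate"
      next
    }
    v[i] <- stats::var(normalize_trace(tr, "minmax"))
    high <- v[i] > threshold
    keep[i] <- if (discard_high) !high else high
    reason[i] <- if (keep[i]) "kept" else "variance"
  }
  out <- subset_components(set, keep)
  attr(out, "variance_report") <- data.frame(id = seq_len(K), variance = v,
                                             kept = keep, reason = reason)
  out
}

#' Summarize a component set as a data frame / CSV
#' @param set a [component_set()].
#' @param path optional CSV output path.
#' @return Data frame: id, centroid (um), voxel count, volume (um^3).
#' @export
components_table <- function(set, path = NULL) {
  stopifnot(inherits(set, "component_set"))
  df <- data.frame(id = seq_along(set$footprints),
                   z_um = set$centroids[, 1], y_um = set$centroids[, 2],
                   x_um = set$centroids[, 3],
                   voxels = set$voxel_count,
                   volume_um3 = set$voxel_count * voxel_volume(set$meta))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
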