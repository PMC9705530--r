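#' Estimate rigid per-volume shifts against a template
#'
#' The template is the voxelwise median of the first `template_frames`
#' volumes (or a user-supplied volume). For every volume the integer shift
#' maximizing the spatial cross-correlation with the template is found in
#' the Fourier domain, refined to sub-voxel precision by quadratic
#' interpolation of the correlation peak along each axis, and clamped to
#' `max_shifts`.
#'
#' The reported shift is the displacement of the volume relative to the
#' template: a volume equal to the template translated by `(dz, dy, dx)`
#' yields exactly that shift, and [apply_shifts()] undoes it.
#'
#' @param movie a [movie4d()].
#' @param max_shifts `(z, y, x)` maximum allowed absolute shift in voxels.
#' @param template_frames number of leading volumes the template median is
#'   taken over.
#' @param template optional explicit template volume `(z, y, x)`.
#' @return An object of class `shift_series`: matrix `shifts` (`t x 3`,
#'   columns dz, dy, dx) plus the template.
#' @export
estimate_shifts <- function(movie, max_shifts = c(2, 4, 4),
                            template_frames = 30L, template = NULL) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  if (is.null(template)) {
    nt0 <- min(template_frames, d[1])
    template <- apply(movie$data[seq_len(nt0), , , , drop = FALSE], 2:4,
                      stats::median)
  }
  if (all(template == 0)) stop("degenerate all-zero template")
  dims <- d[2:4]
  ft <- Conj(stats::fft(template))
  # allowed circular displacements per axis (0, 1, ..., max, n-max, ..., n-1)
  axis_ok <- lapply(1:3, function(ax) {
    n <- dims[ax]
    s <- seq_len(n) - 1L
    disp <- ifelse(s > n / 2, s - n, s)
    abs(disp) <= max_shifts[ax]
  })
  shifts <- matrix(0, d[1], 3)
  for (t in seq_len(d[1])) {
    cc <- Re(stats::fft(stats::fft(movie$data[t, , , ]) * ft,
                        inverse = TRUE)) / prod(dims)
    masked <- cc
    masked[!axis_ok[[1]], , ] <- -Inf
    masked[, !axis_ok[[2]], ] <- -Inf
    masked[, , !axis_ok[[3]]] <- -Inf
    pk <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    sh <- numeric(3)
    for (ax in 1:3) {
      n <- dims[ax]
      i0 <- pk[ax]
      disp <- if (i0 - 1 > n / 2) i0 - 1 - n else i0 - 1
      # quadratic refinement using circular neighbors on the same axis
      ip <- (i0 %% n) + 1L
      im <- ((i0 - 2L) %% n) + 1L
      idx <- pk
      idx[ax] <- im; cm <- cc[idx[1], idx[2], idx[3]]
      idx[ax] <- ip; cp <- cc[idx[1], idx[2], idx[3]]
      c0 <- cc[pk[1], pk[2], pk[3]]
      # quadratic interpolation of the (log-)correlation: exact for a
      # Gaussian-shaped peak, which smooth microscopy content produces
      if (cm > 0 && cp > 0 && c0 > 0) {
        cm <- log(cm); cp <- log(cp); c0 <- log(c0)
      }
      den <- cm - 2 * c0 + cp
      frac <- if (den < 0) 0.5 * (cm - cp) / den else 0
      frac <- max(-0.5, min(0.5, frac))
      sh[ax] <- max(-max_shifts[ax], min(max_shifts[ax], disp + frac))
    }
    shifts[t, ] <- sh
  }
  colnames(shifts) <- c("dz", "dy", "dx")
  structure(list(shifts = shifts, template = template,
                 max_shifts = max_shifts),
            class = "shift_series")
}

#' Apply (undo) estimated rigid shifts
#'
#' Each volume is translated by minus its estimated shift with trilinear
#' interpolation; voxels shifted in from outside the field are filled with
#' the volume's median.
#'
#' @param movie a [movie4d()].
#' @param shifts a `shift_series` from [estimate_shifts()] (or a `t x 3`
#'   matrix of shifts).
#' @return The motion-corrected [movie4d()].
#' @export
apply_shifts <- function(movie, shifts) {
  stopifnot(inherits(movie, "movie4d"))
  s <- if (inherits(shifts, "shift_series")) shifts$shifts else shifts
  d <- dim(movie$data)
  if (nrow(s) != d[1]) {
    stop("shift series length ", nrow(s), " does not match ", d[1], " volumes")
  }
  out <- movie$data
  for (t in seq_len(d[1])) {
    if (any(s[t, ] != 0)) {
      vol <- movie$data[t, , , ]
      out[t, , , ] <- shift_volume(vol, -s[t, ])
    }
  }
  new_movie4d(out, movie$meta)
}

#' Export a shift series as a data frame / CSV
#' @param shifts a `shift_series`.
#' @param path optional CSV output path.
#' @return Data frame with columns `t`, `dz`, `dy`, `dx`.
#' @export
shifts_table <- function(shifts, path = NULL) {
  stopifnot(inherits(shifts, "shift_series"))
  df <- data.frame(t = seq_len(nrow(shifts$shifts)), shifts$shifts)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
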