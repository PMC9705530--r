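#' Extraction parameters
#'
#' Parameters of the constrained matrix-factorization source extraction.
#' Defaults follow the published processing configuration: `K = 10`
#' components per seeding patch, expected component half-width
#' `gSig = (2, 2, 2)` voxels, merge threshold 0.8, `nb = 2` background
#' components, AR order `p = 2` (recorded only; temporal deconvolution is
#' not part of the factorization core), acceptance thresholds peak
#' SNR >= 1 and spatial correlation >= 0.5, and patch geometry
#' `rf = 10`, `stride = 10` (used for seeding tiles; fitting is
#' whole-volume at the scales this package targets).
#'
#' @param K maximum components per seeding patch.
#' @param gSig expected half-width of a component, voxels, `(z, y, x)`.
#' @param merge_thresh trace correlation above which spatially overlapping
#'   components are merged.
#' @param nb rank of the low-rank background term.
#' @param p autoregressive order of the indicator dynamics (recorded).
#' @param min_snr minimum peak SNR for acceptance.
#' @param min_spatial_corr minimum footprint/movie spatial correlation.
#' @param rf,stride patch half-size and stride, voxels (seeding tiles).
#' @param n_iter maximum alternating-update iterations.
#' @param tol relative reconstruction-error change for convergence.
#' @param spatial_thresh final footprint cleanup: voxels with weight below
#'   this fraction of the footprint maximum are removed (the conventional
#'   post-fit spatial thresholding of CNMF implementations; trims the faint
#'   out-of-focus halo that the factorization rightly assigns to each
#'   neuron but that does not belong to its soma).
#' @param min_corr minimum smoothed-correlation-image value for a seed (the
#'   standard seed-quality gate of correlation-image initialization); the
#'   correlation image of structureless noise stays near zero, so this
#'   keeps pure-noise movies from seeding components at all.
#' @return An object of class `extract_params`.
#' @export
extract_params <- function(K = 10L, gSig = c(2, 2, 2), merge_thresh = 0.8,
                           nb = 2L, p = 2L, min_snr = 1.0,
                           min_spatial_corr = 0.5, rf = 10L, stride = 10L,
                           n_iter = 30L, tol = 1e-4, spatial_thresh = 0.25,
                           min_corr = 0.2) {
  stopifnot(K >= 1, merge_thresh > 0, merge_thresh <= 1, nb >= 0)
  gSig <- rep_len(gSig, 3)
  structure(as.list(environment()), class = "extract_params")
}

#' Temporal-correlation image
#'
#' For every voxel, the mean temporal Pearson correlation with its
#' 6-connected neighbors. Voxels belonging to a neuron share a trace and
#' score high; independent-noise voxels score near zero. Zero-variance
#' voxels contribute 0.
#'
#' @param movie a [movie4d()] with at least 2 volumes.
#' @return 3D array `(z, y, x)` of values in `[-1, 1]`.
#' @export
correlation_image <- function(movie) {
  stopifnot(inherits(movie, "movie4d"))
  d <- dim(movie$data)
  if (d[1] < 2) stop("correlation image needs at least 2 time points")
  dims <- d[2:4]
  nv <- prod(dims)
  y <- matrix(aperm(movie$data, c(2, 3, 4, 1)), nv, d[1])
  y <- y - rowMeans(y)
  sd_ <- sqrt(rowSums(y^2))
  ok <- sd_ > 0
  y[ok, ] <- y[ok, ] / sd_[ok]
  y[!ok, ] <- 0  # zero-variance voxels: correlation contribution 0
  acc <- array(0, dims)
  cnt <- array(0, dims)
  z <- array(y, c(dims, d[1]))
  for (ax in 1:3) {
    n <- dims[ax]
    if (n < 2) next
    idx_a <- switch(ax, z[1:(n - 1), , , , drop = FALSE],
                    z[, 1:(n - 1), , , drop = FALSE],
                    z[, , 1:(n - 1), , drop = FALSE])
    idx_b <- switch(ax, z[2:n, , , , drop = FALSE],
                    z[, 2:n, , , drop = FALSE],
                    z[, , 2:n, , drop = FALSE])
    corr <- apply(idx_a * idx_b, 1:3, sum)
    pad0 <- function(a, side) {
      dd <- dim(a)
      dd[ax] <- 1
      zero <- array(0, dd)
      if (side == "before") {
        switch(ax, abind_ax(zero, a, 1), abind_ax(zero, a, 2),
               abind_ax(zero, a, 3))
      } else {
        switch(ax, abind_ax(a, zero, 1), abind_ax(a, zero, 2),
               abind_ax(a, zero, 3))
      }
    }
    acc <- acc + pad0(corr, "after") + pad0(corr, "before")
    ones <- array(1, dim(corr))
    cnt <- cnt + pad0(ones, "after") + pad0(ones, "before")
  }
  cnt[cnt == 0] <- 1
  acc / cnt
}

# bind two 3D arrays along one axis
abind_ax <- function(a, b, ax) {
  da <- dim(a); db <- dim(b)
  dd <- da; dd[ax] <- da[ax] + db[ax]
  out <- array(0, dd)
  ia <- lapply(seq_along(dd), function(i) seq_len(da[i]))
  ib <- lapply(seq_along(dd), function(i)
    if (i == ax) da[ax] + seq_len(db[ax]) else seq_len(db[i]))
  out[ia[[1]], ia[[2]], ia[[3]]] <- a
  out[ib[[1]], ib[[2]], ib[[3]]] <- b
  out
}

#' Seed component centers from a correlation image
#'
#' Smooths the correlation image at the expected component scale `gSig`,
#' finds strict 26-connected local maxima with smoothed value at least
#' `min_corr`, enforces a minimum separation of `2 * gSig` (greedy,
#' strongest first; ties broken by lexicographic (z, y, x) order), and
#' keeps the top `K` per seeding tile of side `2 * rf`.
#'
#' @param corr 3D correlation image (all finite).
#' @param params an [extract_params()].
#' @return Integer matrix `n x 3` of seed centers (z, y, x), possibly empty,
#'   in descending smoothed-correlation order.
#' @export
seed_components <- function(corr, params = extract_params()) {
  stopifnot(all(is.finite(corr)))
  dims <- dim(corr)
  sm <- gauss_smooth3(corr, params$gSig)
  is_max <- array(TRUE, dims)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- seq_len(dims[1]) + dz
    sy <- seq_len(dims[2]) + dy
    sx <- seq_len(dims[3]) + dx
    okz <- sz >= 1 & sz <= dims[1]
    oky <- sy >= 1 & sy <= dims[2]
    okx <- sx >= 1 & sx <= dims[3]
    nb <- array(-Inf, dims)
    nb[okz, oky, okx] <- sm[sz[okz], sy[oky], sx[okx]]
    is_max <- is_max & (sm > nb)
  }
  cand <- which(is_max & sm >= params$min_corr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(matrix(integer(), 0, 3,
                                     dimnames = list(NULL, c("z", "y", "x"))))
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  sep <- 2 * params$gSig
  kept <- matrix(0L, 0, 3)
  keptv <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) > 0) {
      dd <- sweep(kept, 2, cand[i, ])
      dd <- sweep(dd, 2, pmax(sep, 1e-9), "/")
      if (min(rowSums(dd^2)) < 1) next
    }
    kept <- rbind(kept, cand[i, ])
    keptv <- c(keptv, vals[i])
  }
  # top-K per tile of side 2*rf
  tile <- floor(sweep(kept - 1L, 2, rep(2 * params$rf, 3), "%/%"))
  tid <- paste(tile[, 1], tile[, 2], tile[, 3])
  take <- unlist(lapply(split(seq_len(nrow(kept)), tid), function(ii) {
    ii[order(-keptv[ii])][seq_len(min(params$K, length(ii)))]
  }), use.names = FALSE)
  take <- take[order(-keptv[take], kept[take, 1], kept[take, 2],
                     kept[take, 3])]
  out <- kept[take, , drop = FALSE]
  colnames(out) <- c("z", "y", "x")
  out
}

# linear indices of a box around a center (or bounding box), clamped to dims
box_indices <- function(lo, hi, dims) {
  lo <- pmax(1L, lo); hi <- pmin(dims, hi)
  gz <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gx <- lo[3]:hi[3]
  as.integer(outer(outer(gz, (gy - 1L) * dims[1], "+"),
                   (gx - 1L) * dims[1] * dims[2], "+"))
}

idx_to_zyx <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  x <- idx0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

#' Fit the constrained factorization Y = AC + B + E
#'
#' Block-coordinate (hierarchical) alternating nonnegative least squares.
#' Footprints are initialized as Gaussian bumps of scale `gSig` at the
#' seeds and updated voxelwise under nonnegativity, restricted to a support
#' box (side `4*gSig + 1` around the seed, updated each iteration to the
#' footprint's current bounding box); traces are updated by nonnegative
#' least squares given the footprints and background; the background is the
#' rank-`nb` truncated SVD of the activity residual `Y - AC` (the optimal
#' rank-`nb` approximation, so every update leaves the objective
#' `||Y - AC - B||^2` non-increasing). Iteration stops after `n_iter`
#' rounds or when the relative change of the reconstruction error falls
#' below `tol`.
#'
#' @param movie a [movie4d()] (no NaNs).
#' @param seeds integer matrix `n x 3` of seed voxels (z, y, x).
#' @param params an [extract_params()].
#' @param n_iter,tol override the iteration budget / tolerance in `params`.
#' @return An object of class `factor_model`: `A` (list of footprints as
#'   `idx`/`w` pairs over the `(z, y, x)` volume), `C` (`K x T` traces),
#'   `b`, `f` (background factors, possibly 0-rank), `dims`, `meta`,
#'   `objective` (per-iteration reconstruction errors).
#' @export
fit_model <- function(movie, seeds, params = extract_params(),
                      n_iter = params$n_iter, tol = params$tol) {
  stopifnot(inherits(movie, "movie4d"))
  if (anyNA(movie$data)) stop("movie contains NaN/NA values")
  seeds <- matrix(as.integer(seeds), ncol = 3)
  if (nrow(seeds) == 0) stop("fit_model requires at least one seed")
  d <- dim(movie$data)
  dims <- d[2:4]
  nv <- prod(dims)
  nt <- d[1]
  K <- nrow(seeds)
  Y <- t(matrix(movie$data, nt, nv))  # nv x nt
  half <- as.integer(2 * params$gSig)  # box side 4*gSig + 1

  A_idx <- vector("list", K)
  A_w <- vector("list", K)
  for (i in seq_len(K)) {
    idx <- box_indices(seeds[i, ] - half, seeds[i, ] + half, dims)
    zyx <- idx_to_zyx(idx, dims)
    d2 <- rowSums(sweep(sweep(zyx, 2, as.numeric(seeds[i, ])), 2,
                        pmax(params$gSig, 0.5), "/")^2)
    A_idx[[i]] <- idx
    A_w[[i]] <- exp(-d2 / 2)
  }
  C <- matrix(0, K, nt)
  for (i in seq_len(K)) {
    w <- A_w[[i]]
    tr <- as.numeric(crossprod(w, Y[A_idx[[i]], , drop = FALSE])) / sum(w^2)
    C[i, ] <- pmax(0, tr - stats::median(tr))
  }
  bf <- list(b = matrix(0, nv, 0), f = matrix(0, 0, nt))

  resid_full <- function() {
    R <- Y
    for (i in seq_len(K)) {
      R[A_idx[[i]], ] <- R[A_idx[[i]], ] - A_w[[i]] %o% C[i, ]
    }
    if (ncol(bf$b) > 0) R <- R - bf$b %*% bf$f
    R
  }

  update_background <- function(R_plus_B) {
    if (params$nb == 0) return(list(b = matrix(0, nv, 0),
                                    f = matrix(0, 0, nt)))
    G <- crossprod(R_plus_B)  # nt x nt
    eg <- eigen(G, symmetric = TRUE)
    nb <- min(params$nb, nt)
    f <- t(eg$vectors[, seq_len(nb), drop = FALSE])
    b <- R_plus_B %*% t(f)
    list(b = b, f = f)
  }

  obj <- numeric(0)
  R <- resid_full()
  for (it in seq_len(n_iter)) {
    # background update on Y - AC (optimal rank-nb approximation)
    RB <- R + if (ncol(bf$b) > 0) bf$b %*% bf$f else 0
    bf <- update_background(RB)
    R <- RB - if (ncol(bf$b) > 0) bf$b %*% bf$f else 0
    # HALS sweeps over components: spatial then temporal update
    for (i in seq_len(K)) {
      idx <- A_idx[[i]]
      w <- A_w[[i]]
      # residual without component i on its current support
      R[idx, ] <- R[idx, ] + w %o% C[i, ]
      cn <- sum(C[i, ]^2)
      w_new <- if (cn > 0) {
        pmax(0, as.numeric(R[idx, , drop = FALSE] %*% C[i, ]) / cn)
      } else w
      if (any(w_new > 0)) {
        # shrink support to current bounding box (keeps footprints compact)
        zyx <- idx_to_zyx(idx[w_new > 0], dims)
        lo <- apply(zyx, 2, min); hi <- apply(zyx, 2, max)
        nidx <- box_indices(lo, hi, dims)
        w2 <- numeric(length(nidx))
        pos <- match(idx, nidx)
        inb <- !is.na(pos)
        w2[pos[inb]] <- w_new[inb]
        idx <- nidx
        w_new <- w2
      }
      an <- sum(w_new^2)
      c_new <- if (an > 0) {
        pmax(0, as.numeric(crossprod(w_new, R[idx, , drop = FALSE])) / an)
      } else C[i, ]
      R[idx, ] <- R[idx, ] - w_new %o% c_new
      A_idx[[i]] <- idx
      A_w[[i]] <- w_new
      C[i, ] <- c_new
    }
    obj <- c(obj, sqrt(sum(R^2)))
    if (it > 1 && abs(obj[it - 1] - obj[it]) <=
        tol * max(obj[it - 1], .Machine$double.eps)) break
  }

  A <- lapply(seq_len(K), function(i) {
    keep <- A_w[[i]] > 0
    list(idx = A_idx[[i]][keep], w = A_w[[i]][keep], seed = seeds[i, ])
  })
  structure(list(A = A, C = C, b = bf$b, f = bf$f, dims = dims,
                 meta = movie$meta, objective = obj),
            class = "factor_model")
}

#' Residual of a fitted factor model
#'
#' Materializes `E = Y - AC - B` for a movie and its fitted model.
#'
#' @param model a `factor_model`.
#' @param movie the [movie4d()] the model was fitted to.
#' @return `nv x nt` residual matrix.
#' @export
model_residual <- function(model, movie) {
  d <- dim(movie$data)
  Y <- t(matrix(movie$data, d[1], prod(model$dims)))
  for (i in seq_along(model$A)) {
    a <- model$A[[i]]
    if (length(a$idx)) Y[a$idx, ] <- Y[a$idx, ] - a$w %o% model$C[i, ]
  }
  if (ncol(model$b) > 0) Y <- Y - model$b %*% model$f
  Y
}

#' Evaluate fitted components
#'
#' Per component: the peak SNR, `(max(C) - median(C)) / sigma` with `sigma`
#' the robust noise level of the trace (1.4826 times the MAD of the first
#' differences, divided by sqrt(2)), and the spatial correlation, the
#' Pearson correlation between the footprint and the movie averaged over
#' the frames where the trace is in its top decile, computed on the
#' footprint's bounding box. A component is accepted iff peak
#' SNR >= `min_snr` and spatial correlation >= `min_spatial_corr`.
#'
#' @param model a `factor_model`.
#' @param movie the fitted [movie4d()].
#' @param min_snr,min_spatial_corr acceptance thresholds.
#' @return Data frame with `snr`, `spatial_corr`, `accepted` per component.
#' @export
evaluate_components <- function(model, movie, min_snr = 1.0,
                                min_spatial_corr = 0.5) {
  stopifnot(inherits(model, "factor_model"), inherits(movie, "movie4d"))
  K <- length(model$A)
  if (K == 0) {
    return(data.frame(snr = numeric(0), spatial_corr = numeric(0),
                      accepted = logical(0)))
  }
  d <- dim(movie$data)
  Y <- t(matrix(movie$data, d[1], prod(model$dims)))
  snr <- numeric(K)
  sc <- numeric(K)
  for (i in seq_len(K)) {
    tr <- model$C[i, ]
    snr[i] <- peak_snr(tr)
    a <- model$A[[i]]
    if (length(a$idx) == 0 || stats::sd(tr) == 0) {
      sc[i] <- 0
      next
    }
    zyx <- idx_to_zyx(a$idx, model$dims)
    lo <- apply(zyx, 2, min); hi <- apply(zyx, 2, max)
    bidx <- box_indices(lo, hi, model$dims)
    w <- numeric(length(bidx))
    w[match(a$idx, bidx)] <- a$w
    top <- tr >= stats::quantile(tr, 0.9)
    img <- rowMeans(Y[bidx, top, drop = FALSE])
    sc[i] <- if (stats::sd(w) > 0 && stats::sd(img) > 0) {
      stats::cor(w, img)
    } else 0
  }
  data.frame(snr = snr, spatial_corr = sc,
             accepted = snr >= min_snr & sc >= min_spatial_corr)
}

# do two footprints share any voxel?
fp_overlap <- function(a, b) length(intersect(a$idx, b$idx)) > 0

#' Merge redundant components
#'
#' Components whose footprints spatially overlap and whose traces correlate
#' at or above `merge_thresh` are merged transitively (connected components
#' of the overlap-and-correlation graph): footprints are summed and the
#' merged trace is refit by nonnegative least squares against the movie
#' residual. Repeats until no eligible pair remains.
#'
#' @param model a `factor_model`.
#' @param movie the fitted [movie4d()] (used to refit merged traces).
#' @param merge_thresh trace Pearson correlation threshold.
#' @return A `factor_model` with merged components.
#' @export
merge_components <- function(model, movie, merge_thresh = 0.8) {
  stopifnot(inherits(model, "factor_model"))
  repeat {
    K <- length(model$A)
    if (K < 2) return(model)
    adj <- matrix(FALSE, K, K)
    trc <- stats::cor(t(model$C))
    trc[is.na(trc)] <- 0
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      adj[i, j] <- adj[j, i] <-
        fp_overlap(model$A[[i]], model$A[[j]]) && trc[i, j] >= merge_thresh
    }
    if (!any(adj)) return(model)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    d <- dim(movie$data)
    Y <- t(matrix(movie$data, d[1], prod(model$dims)))
    B <- if (ncol(model$b) > 0) model$b %*% model$f else NULL
    newA <- list()
    newC <- NULL
    for (grp in sort(unique(comp))) {
      members <- which(comp == grp)
      if (length(members) == 1) {
        newA[[length(newA) + 1]] <- model$A[[members]]
        newC <- rbind(newC, model$C[members, ])
        next
      }
      idx <- sort(unique(unlist(lapply(members, function(i)
        model$A[[i]]$idx))))
      w <- numeric(length(idx))
      for (i in members) {
        w[match(model$A[[i]]$idx, idx)] <-
          w[match(model$A[[i]]$idx, idx)] + model$A[[i]]$w
      }
      Ri <- Y[idx, , drop = FALSE]
      if (!is.null(B)) Ri <- Ri - B[idx, , drop = FALSE]
      for (i in setdiff(seq_len(K), members)) {
        a <- model$A[[i]]
        common <- intersect(idx, a$idx)
        if (length(common)) {
          Ri[match(common, idx), ] <- Ri[match(common, idx), ] -
            a$w[match(common, a$idx)] %o% model$C[i, ]
        }
      }
      cm <- pmax(0, as.numeric(crossprod(w, Ri)) / sum(w^2))
      newA[[length(newA) + 1]] <- list(idx = idx, w = w,
                                       seed = model$A[[members[1]]]$seed)
      newC <- rbind(newC, cm)
    }
    model$A <- newA
    model$C <- matrix(newC, nrow = length(newA))
  }
}

#' Run the full two-pass extraction
#'
#' Pass 1: seed from the correlation image, fit the factorization, evaluate
#' and keep accepted components. Pass 2: refit the whole volume seeded with
#' the accepted components only, merge redundant components, and evaluate
#' again. Returns the accepted components with their footprints, denoised
#' traces, raw traces (movie averaged over the footprint support),
#' centroids (micrometres) and voxel counts.
#'
#' @param movie a preprocessed, motion-corrected [movie4d()].
#' @param params an [extract_params()].
#' @return A `component_set` (see [component_set()]); empty with a warning
#'   when nothing is accepted.
#' @export
run_extraction <- function(movie, params = extract_params()) {
  stopifnot(inherits(movie, "movie4d"))
  corr <- correlation_image(movie)
  seeds <- seed_components(corr, params)
  if (nrow(seeds) == 0) {
    warning("no seeds found; returning an empty component set")
    return(component_set(list(), matrix(0, 0, dim(movie$data)[1]),
                         matrix(0, 0, dim(movie$data)[1]), movie$meta,
                         dim(movie$data)[2:4]))
  }
  m1 <- fit_model(movie, seeds, params)
  ev1 <- evaluate_components(m1, movie, params$min_snr,
                             params$min_spatial_corr)
  keep <- which(ev1$accepted)
  if (length(keep) == 0) {
    warning("no components accepted; returning an empty component set")
    return(component_set(list(), matrix(0, 0, dim(movie$data)[1]),
                         matrix(0, 0, dim(movie$data)[1]), movie$meta,
                         dim(movie$data)[2:4]))
  }
  seeds2 <- do.call(rbind, lapply(keep, function(i) {
    a <- m1$A[[i]]
    zyx <- idx_to_zyx(a$idx, m1$dims)
    round(colSums(zyx * a$w) / sum(a$w))
  }))
  m2 <- fit_model(movie, seeds2, params)
  m2 <- merge_components(m2, movie, params$merge_thresh)
  ev2 <- evaluate_components(m2, movie, params$min_snr,
                             params$min_spatial_corr)
  keep2 <- which(ev2$accepted)
  if (length(keep2) == 0) {
    warning("no components accepted after refit; returning an empty set")
    return(component_set(list(), matrix(0, 0, dim(movie$data)[1]),
                         matrix(0, 0, dim(movie$data)[1]), movie$meta,
                         dim(movie$data)[2:4]))
  }
  d <- dim(movie$data)
  Y <- t(matrix(movie$data, d[1], prod(m2$dims)))
  fps <- lapply(m2$A[keep2], function(a) {
    keep <- a$w >= params$spatial_thresh * max(a$w)
    list(idx = a$idx[keep], w = a$w[keep])
  })
  raw <- t(vapply(fps, function(a)
    colMeans(Y[a$idx, , drop = FALSE]), numeric(d[1])))
  component_set(fps, m2$C[keep2, , drop = FALSE], raw, movie$meta, m2$dims,
                evaluation = ev2[keep2, ])
}
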