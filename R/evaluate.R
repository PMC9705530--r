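#' Consensus of independent annotations
#'
#' Voxelwise logical AND across annotator masks: a voxel counts as neuron
#' only when every annotator marked it. Adding an annotator can only
#' shrink the consensus.
#'
#' @param annos list of binary (logical or 0/1) arrays of identical shape;
#'   at least one.
#' @return Logical array, the consensus mask.
#' @export
consensus_annotation <- function(annos) {
  if (length(annos) == 0) stop("need at least one annotation")
  ref <- dim(annos[[1]])
  out <- annos[[1]] > 0
  for (a in annos[-1]) {
    if (!identical(dim(a), ref)) stop("annotation masks differ in shape")
    out <- out & (a > 0)
  }
  out
}

#' Voxel-level segmentation metrics
#'
#' Precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2 P R / (P + R)` of a predicted binary mask against a truth mask,
#' with the convention that a vanishing denominator yields 0.
#'
#' @param pred,truth binary arrays of identical shape.
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
segmentation_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  p <- pred > 0
  t_ <- truth > 0
  tp <- sum(p & t_)
  fp <- sum(p & !t_)
  fn <- sum(!p & t_)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Binarize a footprint for voxel-level scoring
#'
#' A voxel belongs to the binary footprint when its weight exceeds
#' `rel_thresh` times that footprint's maximum weight.
#'
#' @param set a [component_set()].
#' @param rel_thresh relative weight threshold (default 0.1).
#' @return Logical 3D array, the union of all binarized footprints.
#' @export
footprint_mask <- function(set, rel_thresh = 0.1) {
  stopifnot(inherits(set, "component_set"))
  mask <- array(FALSE, set$dims)
  for (f in set$footprints) {
    if (length(f$w) == 0) next
    mask[f$idx[f$w > rel_thresh * max(f$w)]] <- TRUE
  }
  mask
}

# ground-truth binary mask of active neurons
ground_truth_mask <- function(gt) {
  mask <- array(FALSE, gt$dims)
  for (f in gt$footprints) mask[f$idx] <- TRUE
  mask
}

#' Match extracted components to ground truth and score traces
#'
#' Greedy one-to-one matching by footprint Jaccard overlap (descending;
#' pairs below `min_jaccard` never match), then the Pearson correlation of
#' each matched denoised trace with the ground-truth clean trace.
#' Unmatched ground-truth neurons are misses; unmatched components are
#' false positives. The result does not depend on component order.
#'
#' @param set a [component_set()].
#' @param gt a [generate_ground_truth()] result with the same volume
#'   geometry.
#' @param min_jaccard minimum Jaccard overlap for a match (default 0.1).
#' @return List with `matches` (data frame: component, truth, jaccard,
#'   trace_r), `missed` (truth ids), `false_positives` (component ids).
#' @export
match_and_score_traces <- function(set, gt, min_jaccard = 0.1) {
  stopifnot(inherits(set, "component_set"), inherits(gt, "ground_truth"))
  if (!identical(as.integer(set$dims), as.integer(gt$dims))) {
    stop("component set and ground truth differ in volume geometry")
  }
  K <- length(set$footprints)
  n_gt <- length(gt$footprints)
  if (K == 0 || n_gt == 0) {
    return(list(matches = data.frame(component = integer(),
                                     truth = integer(), jaccard = numeric(),
                                     trace_r = numeric()),
                missed = seq_len(n_gt),
                false_positives = seq_len(K)))
  }
  jac <- matrix(0, K, n_gt)
  for (i in seq_len(K)) {
    a <- set$footprints[[i]]$idx
    for (j in seq_len(n_gt)) {
      b <- gt$footprints[[j]]$idx
      inter <- length(intersect(a, b))
      if (inter > 0) jac[i, j] <- inter / length(union(a, b))
    }
  }
  matches <- data.frame(component = integer(), truth = integer(),
                        jaccard = numeric(), trace_r = numeric())
  J <- jac
  repeat {
    m <- max(J)
    if (m < min_jaccard || m == 0) break
    # deterministic tie-break: smallest component id, then truth id
    hits <- which(J == m, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    r <- suppressWarnings(stats::cor(set$traces[i, ], gt$clean_traces[j, ]))
    matches <- rbind(matches, data.frame(component = i, truth = j,
                                         jaccard = m,
                                         trace_r = ifelse(is.na(r), 0, r)))
    J[i, ] <- 0
    J[, j] <- 0
  }
  list(matches = matches,
       missed = setdiff(seq_len(n_gt), matches$truth),
       false_positives = setdiff(seq_len(K), matches$component))
}

#' Ground-truth trace recovery of a movie
#'
#' Averages the movie over each ground-truth footprint and correlates the
#' resulting trace with the neuron's clean trace; reports the per-neuron
#' Pearson correlations. Used to verify that a preprocessing step does not
#' degrade the recoverable activity signal.
#'
#' @param movie a [movie4d()] with the ground truth's geometry.
#' @param gt a [generate_ground_truth()] result.
#' @return Numeric vector of per-neuron correlations (NA for neurons with
#'   a constant clean trace).
#' @export
gt_trace_recovery <- function(movie, gt) {
  stopifnot(inherits(movie, "movie4d"), inherits(gt, "ground_truth"))
  d <- dim(movie$data)
  Y <- t(matrix(movie$data, d[1], prod(gt$dims)))
  vapply(seq_along(gt$footprints), function(i) {
    f <- gt$footprints[[i]]
    tr <- colMeans(Y[f$idx, , drop = FALSE])
    suppressWarnings(stats::cor(tr, gt$clean_traces[i, ]))
  }, numeric(1))
}

#' SNR gain of denoised over raw traces
#'
#' Per component, the ratio of peak SNRs, `(max - median) / noise` with the
#' robust noise level `1.4826 * MAD(diff(trace)) / sqrt(2)`, of the
#' denoised versus the raw trace. A zero raw-noise estimate yields `Inf`; a
#' flat denoised trace yields 0.
#'
#' @param raw_traces,denoised_traces matrices `K x T` of paired traces.
#' @return Numeric vector of per-component gains.
#' @export
snr_gain <- function(raw_traces, denoised_traces) {
  raw_traces <- matrix(raw_traces, nrow = NROW(raw_traces))
  denoised_traces <- matrix(denoised_traces, nrow = NROW(denoised_traces))
  stopifnot(identical(dim(raw_traces), dim(denoised_traces)))
  vapply(seq_len(nrow(raw_traces)), function(i) {
    s_raw <- peak_snr(raw_traces[i, ])
    s_den <- peak_snr(denoised_traces[i, ])
    if (s_den == 0) return(0)
    if (is.infinite(s_raw) && is.infinite(s_den)) return(1)
    if (s_raw == 0 || is.infinite(s_den)) return(Inf)
    s_den / s_raw
  }, numeric(1))
}
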