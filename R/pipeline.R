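#' Full pipeline configuration
#'
#' Collects every stage parameter with the published defaults: Fourier
#' variance quantile 0.99; rigid-shift bounds (2, 4, 4) voxels in
#' (z, y, x); factorization K = 10, gSig = (2, 2, 2), merge threshold 0.8,
#' nb = 2, p = 2, rf = 10, stride = 10; acceptance thresholds peak
#' SNR >= 1 and spatial correlation >= 0.5; volume bounds 710-7605 um^3;
#' normalized-trace variance threshold 0.06; connectivity threshold
#' |R| > 0.8. The patch motion-correction parameters of the reference
#' configuration (strides (18, 18, 4), overlaps (9, 9, 2),
#' max_deviation_rigid 5) are recorded for provenance; the correction
#' itself is rigid.
#'
#' @param fourier_quantile variance quantile for [fourier_filter()].
#' @param max_shifts rigid-shift clamp `(z, y, x)` voxels.
#' @param template_frames template length for [estimate_shifts()].
#' @param extract an [extract_params()].
#' @param vmin,vmax volume bounds, um^3.
#' @param var_thresh normalized-trace variance threshold.
#' @param graph_threshold absolute Spearman threshold for graph edges.
#' @param normalization trace normalization mode (see [normalize_trace()]).
#' @param use_raw_traces build the Spearman matrix from raw
#'   (footprint-averaged) traces (default) or denoised traces.
#' @param reverse_odd bidirectional reordering parity (NULL: skip
#'   reordering).
#' @param stages character vector of stages to run, in pipeline order.
#' @param seed integer seed.
#' @param patch_motion_params recorded piecewise-rigid parameters
#'   (provenance only).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fourier_quantile = 0.99,
                            max_shifts = c(2, 4, 4),
                            template_frames = 30L,
                            extract = extract_params(),
                            vmin = 710, vmax = 7605,
                            var_thresh = 0.06,
                            graph_threshold = 0.8,
                            normalization = "minmax",
                            use_raw_traces = TRUE,
                            reverse_odd = NULL,
                            stages = c("reorder", "bleach", "fourier",
                                       "motion", "extract", "volume_filter",
                                       "variance_filter", "normalize",
                                       "connectivity"),
                            seed = 0L,
                            patch_motion_params = list(
                              strides = c(18, 18, 4),
                              overlaps = c(9, 9, 2),
                              max_deviation_rigid = 5)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full processing pipeline
#'
#' Stages in order: bidirectional reorder, bleach correction, Fourier
#' stripe/background filter, rigid motion correction, two-pass
#' factorization, volume filter, variance filter, trace normalization, and
#' connectivity (COM ordering, Spearman matrix, thresholded graph). A run
#' manifest records the configuration, seed and a checksum of every
#' stage's output; any stage error aborts with the stage name.
#'
#' @param movie a [movie4d()] or a path readable by [read_hyperstack()].
#' @param config a [pipeline_config()].
#' @param out_dir optional results directory; tables, the manifest and the
#'   graph are written there.
#' @return List with `components` (a [component_set()]), `normalized`
#'   (normalized trace matrix), `ordering`, `correlation`
#'   (`correlation_matrix`), `graph` (`connectivity_graph`), `shifts`,
#'   `fourier_mask`, `manifest`.
#' @export
run_pipeline <- function(movie, config = pipeline_config(), out_dir = NULL) {
  if (is.character(movie)) movie <- read_hyperstack(movie)
  stopifnot(inherits(movie, "movie4d"), inherits(config, "pipeline_config"))
  set.seed(config$seed)
  manifest <- list(config = utils::capture.output(utils::str(config)),
                   seed = config$seed, stages = list())
  log_stage <- function(name, obj, t0) {
    # hash only value semantics (igraph objects carry environments)
    h <- if (inherits(obj, "movie4d")) obj$data
    else if (inherits(obj, "connectivity_graph")) {
      obj[c("nodes", "edges", "threshold")]
    } else obj
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      stage = name, checksum = object_checksum(h),
      seconds = round(as.numeric(Sys.time()) - t0, 3))
  }
  run_stage <- function(name, fn) {
    t0 <- as.numeric(Sys.time())
    obj <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(name, obj, t0)
    obj
  }
  on <- function(s) s %in% config$stages

  if (on("reorder") && !is.null(config$reverse_odd)) {
    movie <- run_stage("reorder", function()
      reorder_bidirectional(movie, config$reverse_odd))
  }
  if (on("bleach")) {
    movie <- run_stage("bleach", function() bleach_correct(movie))
  }
  fmask <- NULL
  if (on("fourier")) {
    ff <- run_stage("fourier", function()
      fourier_filter(movie, config$fourier_quantile))
    movie <- ff$movie
    fmask <- ff$mask
  }
  shifts <- NULL
  if (on("motion")) {
    movie <- run_stage("motion", function() {
      shifts <<- estimate_shifts(movie, config$max_shifts,
                                 config$template_frames)
      apply_shifts(movie, shifts)
    })
  }
  comps <- NULL
  if (on("extract")) {
    comps <- run_stage("extract", function()
      run_extraction(movie, config$extract))
  }
  if (!is.null(comps) && on("volume_filter")) {
    comps <- run_stage("volume_filter", function()
      volume_filter(comps, config$vmin, config$vmax))
  }
  if (!is.null(comps) && on("variance_filter")) {
    comps <- run_stage("variance_filter", function()
      variance_filter(comps, config$var_thresh))
  }
  normalized <- NULL
  if (!is.null(comps) && on("normalize") && length(comps$footprints) > 0) {
    normalized <- run_stage("normalize", function()
      t(apply(comps$traces, 1, normalize_trace, mode = config$normalization)))
  }
  ordering <- NULL
  cm <- NULL
  graph <- NULL
  if (!is.null(comps) && on("connectivity") &&
      length(comps$footprints) >= 2) {
    graph <- run_stage("connectivity", function() {
      ordering <<- order_by_com(comps)
      tr <- if (config$use_raw_traces) comps$raw_traces else comps$traces
      cm <<- spearman_matrix(tr, ordering$order)
      build_graph(cm, config$graph_threshold, comps$centroids)
    })
  }
  out <- list(movie = movie, components = comps, normalized = normalized,
              ordering = ordering, correlation = cm, graph = graph,
              shifts = shifts, fourier_mask = fmask, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(comps) && length(comps$footprints) > 0) {
      components_table(comps, file.path(out_dir, "components.csv"))
    }
    if (!is.null(cm)) {
      utils::write.csv(cm$R, file.path(out_dir, "spearman.csv"),
                       row.names = FALSE)
    }
    if (!is.null(graph)) write_graph_files(graph, out_dir)
    if (!is.null(shifts)) {
      shifts_table(shifts, file.path(out_dir, "shifts.csv"))
    }
  }
  out
}
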