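#' Order components by distance from the center of mass
#'
#' The center of mass (COM) is the unweighted mean of the component
#' centroids; components are ordered by ascending Euclidean distance from
#' it (ties broken by component id).
#'
#' @param set a non-empty [component_set()].
#' @return List with `order` (component ids), `distance` (um, in that
#'   order) and `com` (`(z, y, x)` um).
#' @export
order_by_com <- function(set) {
  stopifnot(inherits(set, "component_set"))
  K <- length(set$footprints)
  if (K == 0) stop("cannot order an empty component set")
  com <- colMeans(set$centroids)
  d <- sqrt(rowSums(sweep(set$centroids, 2, com)^2))
  ord <- order(d, seq_len(K))
  list(order = ord, distance = d[ord], com = com)
}

#' Spearman rank-correlation matrix of traces
#'
#' Pearson correlation of the rank-transformed traces (average ranks for
#' ties), which is invariant under strictly monotone transforms of any
#' trace — robust to amplitude differences from illumination inhomogeneity.
#' A constant trace is rank-degenerate; its row and column are set to 0
#' (diagonal 1) with a warning.
#'
#' @param traces `K x T` matrix (rows are traces), `K >= 2`, `T >= 3`.
#' @param ordering optional permutation of rows (e.g. from
#'   [order_by_com()]); the matrix is returned in that order.
#' @return An object of class `correlation_matrix`: `R` (symmetric, unit
#'   diagonal, values in `[-1, 1]`) and `ids` (component ids in matrix
#'   order).
#' @export
spearman_matrix <- function(traces, ordering = NULL) {
  traces <- as.matrix(traces)
  K <- nrow(traces)
  if (K < 2) stop("need at least 2 traces")
  if (ncol(traces) < 3) stop("traces must have length >= 3")
  ids <- ordering %||% seq_len(K)
  traces <- traces[ids, , drop = FALSE]
  const <- apply(traces, 1, function(x) max(x) == min(x))
  R <- suppressWarnings(stats::cor(t(traces), method = "spearman"))
  if (any(const)) {
    warning("constant trace(s) at position(s) ",
            paste(which(const), collapse = ", "),
            ": rank-degenerate, correlations set to 0")
    R[const, ] <- 0
    R[, const] <- 0
  }
  diag(R) <- 1
  structure(list(R = R, ids = ids), class = "correlation_matrix")
}

#' Thresholded functional-connectivity graph
#'
#' Builds the undirected graph whose nodes are components and whose edges
#' connect pairs with `|R| > threshold` (strict); each edge carries the
#' signed Spearman coefficient, and node degree (the number of incident
#' edges) is recorded for degree-coded display.
#'
#' @param R a `correlation_matrix` from [spearman_matrix()] (or a plain
#'   symmetric matrix).
#' @param threshold absolute-correlation threshold (default 0.8).
#' @param centroids optional `K x 3` matrix of node positions (um), stored
#'   as node attributes.
#' @return An object of class `connectivity_graph`: `nodes` (id, degree,
#'   optional coordinates), `edges` (i, j, R), `graph` (an igraph object)
#'   and `threshold`.
#' @export
build_graph <- function(R, threshold = 0.8, centroids = NULL) {
  ids <- NULL
  if (inherits(R, "correlation_matrix")) {
    ids <- R$ids
    R <- R$R
  }
  K <- nrow(R)
  ids <- ids %||% seq_len(K)
  ut <- which(upper.tri(R) & abs(R) > threshold, arr.ind = TRUE)
  edges <- data.frame(i = ids[ut[, 1]], j = ids[ut[, 2]],
                      R = R[ut])
  deg <- integer(K)
  for (r in seq_len(nrow(ut))) {
    deg[ut[r, 1]] <- deg[ut[r, 1]] + 1L
    deg[ut[r, 2]] <- deg[ut[r, 2]] + 1L
  }
  nodes <- data.frame(id = ids, degree = deg)
  if (!is.null(centroids)) {
    centroids <- centroids[ids, , drop = FALSE]
    nodes$z_um <- centroids[, 1]
    nodes$y_um <- centroids[, 2]
    nodes$x_um <- centroids[, 3]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) data.frame(from = match(edges$i, ids),
                                to = match(edges$j, ids), R = edges$R)
    else data.frame(from = integer(), to = integer(), R = numeric()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(K), id = ids, degree = deg))
  structure(list(nodes = nodes, edges = edges, graph = g,
                 threshold = threshold),
            class = "connectivity_graph")
}

#' Export a connectivity graph
#'
#' Writes the node and edge tables as CSV and, optionally, the graph as
#' GraphML.
#'
#' @param graph a `connectivity_graph`.
#' @param dir output directory (created if needed).
#' @param graphml also write `graph.graphml`.
#' @return `dir`, invisibly.
#' @export
write_graph_files <- function(graph, dir, graphml = TRUE) {
  stopifnot(inherits(graph, "connectivity_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(graph$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(graph$edges, file.path(dir, "edges.csv"),
                   row.names = FALSE)
  if (graphml) {
    igraph::write_graph(graph$graph, file.path(dir, "graph.graphml"),
                        format = "graphml")
  }
  invisible(dir)
}
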