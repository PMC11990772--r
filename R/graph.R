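#' Estimate the neighborhood radius from k-nearest-neighbor distances
#'
#' The alpha-complex radius is taken as the global mean, over spots, of each
#' spot's mean Euclidean distance to its `k` nearest neighbors (self
#' excluded). A single global radius is used for the whole slice.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k number of nearest neighbors.
#' @return positive scalar radius.
#' @export
estimate_radius <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) stop("insufficient-points error: need more points than k (n = ",
                   n, ", k = ", k, ")")
  if (anyDuplicated(coords) > 0)
    warning("duplicate coordinates present; some neighbor distances are 0",
            call. = FALSE)
  res <- RANN::nn2(coords, coords, k = k + 1)
  mean(rowMeans(res$nn.dists[, -1, drop = FALSE]))
}

#' Build the spatial neighbor graph of a slice
#'
#' Computes the Delaunay triangulation of the spot coordinates and keeps
#' the edges of length at most `2r`, with `r` estimated by
#' [estimate_radius()]. For Gabriel edges this equals the alpha-complex
#' condition exactly (the closest point of the shared Voronoi facet is the
#' edge midpoint at distance L/2); non-Gabriel Delaunay edges are slightly
#' over-included. Degenerate geometry (fewer than 3 points, or all points
#' collinear) falls back to a symmetrized k-nearest-neighbor graph with the
#' same `k`, with a warning.
#'
#' @param coords n x 2 coordinate matrix.
#' @param k neighbor count used for the radius estimate (default 6,
#'   matching hexagonal Visium neighborhoods).
#' @return A `spatial_graph` object: `n_spots`, `edges` (2-column index
#'   matrix, i < j), `lengths`, `adjacency` (sparse symmetric 0/1), `radius`,
#'   `k_neighbors`.
#' @export
build_spatial_graph <- function(coords, k = 6) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n <= k) stop("insufficient-points error: need more points than k")
  r <- estimate_radius(coords, k)

  edges <- tryCatch({
    dd <- deldir::deldir(coords[, 1], coords[, 2],
                         suppressMsge = TRUE, round = FALSE)
    es <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
    if (nrow(es) == 0) stop("degenerate triangulation")
    es
  }, error = function(e) NULL)

  fallback <- is.null(edges)
  if (fallback) {
    warning("degenerate geometry: falling back to symmetrized ", k,
            "-nearest-neighbor graph", call. = FALSE)
    idx <- knn_index(coords, k)
    edges <- cbind(rep(seq_len(n), ncol(idx)), as.vector(idx))
  }
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                         coords[edges[, 2], , drop = FALSE])^2))
  if (!fallback) {
    keep <- len <= 2 * r  # closed threshold: exact ties included
    edges <- edges[keep, , drop = FALSE]
    len <- len[keep]
  }
  structure(
    list(n_spots = n, edges = edges, lengths = len,
         adjacency = adjacency_from_edges(edges, n),
         radius = r, k_neighbors = k, fallback = fallback),
    class = "spatial_graph"
  )
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph> ", x$n_spots, " spots, ", nrow(x$edges),
      " edges, radius ", signif(x$radius, 5),
      if (isTRUE(x$fallback)) " (kNN fallback)" else "", "\n", sep = "")
  invisible(x)
}

#' Symmetric degree-normalized adjacency operator
#'
#' Returns the graph-convolution propagation operator
#' \eqn{\tilde D^{-1/2}(A + I)\tilde D^{-1/2}} where \eqn{\tilde D} is the
#' degree matrix of \eqn{A + I}. Isolated nodes reduce to a self-loop of
#' weight 1.
#'
#' @param graph a `spatial_graph`, or a sparse/dense 0/1 adjacency matrix.
#' @return sparse symmetric n x n operator with spectral radius at most 1.
#' @export
normalize_adjacency <- function(graph) {
  A <- if (inherits(graph, "spatial_graph")) graph$adjacency else graph
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  Ai <- A + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Ai))
  Matrix::Diagonal(n, dinv) %*% Ai %*% Matrix::Diagonal(n, dinv)
}

#' Export graph edges as a table
#'
#' @param graph a `spatial_graph`.
#' @param path optional TSV output path (columns `i`, `j`, `length`).
#' @return data.frame of edges, invisibly when written to file.
#' @export
export_edges <- function(graph, path = NULL) {
  df <- data.frame(i = graph$edges[, 1], j = graph$edges[, 2],
                   length = graph$lengths)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
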