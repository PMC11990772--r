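#' Communal attribute-masking weights
#'
#' Per-gene masking weights from community voting: each gene's raw score is
#' the absolute value of its expression summed within communities and
#' weighted by community strength, \eqn{|X^\top H S|}, min-max normalized to
#' `[0, 1]` (an all-equal score vector maps to constant 0.5). Genes with
#' higher weight are more likely to be masked — they carry more
#' community-specific signal, so masking them forces the encoder to rely on
#' context.
#'
#' @param X n x m expression matrix (normalized).
#' @param partition a `community_partition` with strengths.
#' @return length-m numeric vector of weights in `[0, 1]`.
#' @export
attribute_mask_weights <- function(X, partition) {
  stopifnot(nrow(X) == nrow(partition$H))
  hs <- as.vector(partition$H %*% partition$strengths)  # per-spot strength
  raw <- abs(as.vector(crossprod(X, hs)))
  minmax_norm(raw)
}

#' Communal edge-dropping weights
#'
#' Per-edge keep weights: an intra-community edge scores the strength of its
#' community, an inter-community edge scores minus the sum of its two
#' endpoint community strengths; scores are min-max normalized to `[0, 1]`
#' over all edges (all-equal maps to 0.5). Intra-community edges of strong
#' communities therefore have the highest keep weight and cross-community
#' edges the lowest.
#'
#' @param graph a `spatial_graph`.
#' @param partition a `community_partition` with strengths.
#' @return numeric vector, one weight per edge of `graph`.
#' @export
edge_mask_weights <- function(graph, partition) {
  m <- nrow(graph$edges)
  if (m == 0) return(numeric(0))
  hs <- as.vector(partition$H %*% partition$strengths)
  si <- hs[graph$edges[, 1]]
  sj <- hs[graph$edges[, 2]]
  intra <- partition$assignment[graph$edges[, 1]] ==
    partition$assignment[graph$edges[, 2]]
  raw <- ifelse(intra, si, -(si + sj))
  minmax_norm(raw)
}

new_augmented_view <- function(X, graph, attr_keep, edge_keep) {
  keep_mat <- matrix(rep(attr_keep, each = nrow(X)), nrow(X), ncol(X))
  edges_kept <- graph$edges[edge_keep == 1, , drop = FALSE]
  structure(
    list(X_masked = X * keep_mat,
         adjacency_masked = adjacency_from_edges(edges_kept, graph$n_spots),
         attr_mask = keep_mat,
         edge_mask = edge_keep,
         edges_kept = edges_kept),
    class = "augmented_view"
  )
}

#' Sample a community-guided augmented view
#'
#' Draws one augmented view of a slice's graph. Gene columns are kept with
#' probability \eqn{1 - w_g \, p_{attr}} (communal attribute voting; the
#' mask is broadcast across spots) and each edge is kept with probability
#' \eqn{w_e \, p_{edge}} (communal edge dropping), both clipped to `[0, 1]`.
#' An optional floor lifts the minimum edge keep probability.
#'
#' @param X n x m expression matrix.
#' @param graph a `spatial_graph`.
#' @param partition a `community_partition` with strengths.
#' @param p_attr attribute masking hyperparameter in `[0, 1]`.
#' @param p_edge edge keep hyperparameter in `[0, 1]`.
#' @param edge_keep_floor minimum edge keep probability (default 0).
#' @param attr_weights,edge_weights optional precomputed weights (recomputed
#'   from the partition when `NULL`).
#' @return An `augmented_view`: `X_masked`, `adjacency_masked`, `attr_mask`,
#'   `edge_mask`.
#' @export
sample_view <- function(X, graph, partition, p_attr, p_edge,
                        edge_keep_floor = 0,
                        attr_weights = NULL, edge_weights = NULL) {
  stopifnot(p_attr >= 0, p_attr <= 1, p_edge >= 0, p_edge <= 1)
  if (is.null(attr_weights)) attr_weights <- attribute_mask_weights(X, partition)
  if (is.null(edge_weights)) edge_weights <- edge_mask_weights(graph, partition)
  keep_p <- pmin(pmax(1 - attr_weights * p_attr, 0), 1)
  attr_keep <- stats::rbinom(length(keep_p), 1, keep_p)
  ekeep_p <- pmin(pmax(pmax(edge_weights * p_edge, edge_keep_floor), 0), 1)
  edge_keep <- if (length(ekeep_p)) stats::rbinom(length(ekeep_p), 1, ekeep_p)
               else integer(0)
  new_augmented_view(X, graph, attr_keep, edge_keep)
}

#' Sample a uniformly random augmented view
#'
#' Stage-1 perturbation: every gene column is masked independently with
#' probability `p_attr` and every edge dropped with probability
#' `p_edge_drop`, with no community weighting.
#'
#' @param X n x m expression matrix.
#' @param graph a `spatial_graph`.
#' @param p_attr per-gene masking probability.
#' @param p_edge_drop per-edge dropping probability.
#' @return An `augmented_view`.
#' @export
random_view <- function(X, graph, p_attr, p_edge_drop) {
  stopifnot(p_attr >= 0, p_attr <= 1, p_edge_drop >= 0, p_edge_drop <= 1)
  attr_keep <- stats::rbinom(ncol(X), 1, 1 - p_attr)
  m <- nrow(graph$edges)
  edge_keep <- if (m) stats::rbinom(m, 1, 1 - p_edge_drop) else integer(0)
  new_augmented_view(X, graph, attr_keep, edge_keep)
}
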