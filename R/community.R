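#' Detect communities on the spatial graph
#'
#' Runs Leiden modularity optimization on the spatial neighbor graph with
#' edge weights given by the cosine similarity (clipped at zero) between the
#' endpoint feature vectors — the normalized expression profiles
#' (`mode = "expression"`) or a low-dimensional embedding
#' (`mode = "embedding"`). Weighting the spatial edges by expression keeps
#' communities spatially contiguous while still expression-driven.
#'
#' @param slice an [st_slice] in state `"log_normalized"` (ignored for
#'   `mode = "embedding"` except for validation).
#' @param graph a `spatial_graph` for the slice.
#' @param mode `"expression"` or `"embedding"`.
#' @param embedding n x h matrix, required when `mode = "embedding"`.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return A `community_partition`: `assignment` (0-based community index
#'   per spot), `H` (n x C 0/1 indicator), `strengths` (per-community
#'   strength, sums to the partition modularity), `n_communities`.
#' @export
detect_communities <- function(slice, graph, mode = c("expression",
                                                      "embedding"),
                               embedding = NULL, resolution = 1.0,
                               seed = 0) {
  mode <- match.arg(mode)
  if (mode == "embedding") {
    if (is.null(embedding)) stop("mode = 'embedding' requires an embedding")
    feats <- as.matrix(embedding)
  } else {
    validate_slice(slice)
    if (slice$state != "log_normalized")
      stop("expression-mode community detection needs a log_normalized slice")
    feats <- slice$X
  }
  n <- graph$n_spots
  if (nrow(feats) != n) stop("feature rows do not match graph size")

  if (nrow(graph$edges) == 0) {
    warning("graph has no edges; returning a single community", call. = FALSE)
    assignment <- rep(0L, n)
  } else {
    U <- l2_normalize_rows(feats)
    w <- rowSums(U[graph$edges[, 1], , drop = FALSE] *
                   U[graph$edges[, 2], , drop = FALSE])
    w <- pmax(w, 0)
    g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    set.seed(seed)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 weights = w + 1e-12,
                                 resolution = resolution, n_iterations = 5)
    assignment <- as.integer(cl$membership) - 1L
    # relabel to consecutive 0..C-1 in order of first appearance
    assignment <- as.integer(factor(assignment,
                                    levels = unique(assignment))) - 1L
  }
  partition_from_assignment(assignment, graph)
}

partition_from_assignment <- function(assignment, graph = NULL) {
  C <- max(assignment) + 1L
  n <- length(assignment)
  H <- matrix(0, n, C)
  H[cbind(seq_len(n), assignment + 1L)] <- 1
  part <- structure(
    list(assignment = assignment, H = H, strengths = NULL,
         n_communities = C),
    class = "community_partition"
  )
  if (!is.null(part) && !is.null(graph) && nrow(graph$edges) > 0) {
    part$strengths <- community_strength(part, graph)
  } else if (!is.null(graph)) {
    part$strengths <- rep(0, C)
  }
  part
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", length(x$assignment), " spots in ",
      x$n_communities, " communities\n", sep = "")
  invisible(x)
}

#' Per-community strength scores
#'
#' The strength of community \eqn{c} is its modularity contribution
#' \deqn{S_c = E_c/|E| - \left(\sum_{v \in c} d_v\right)^2 / (4|E|^2)}
#' where \eqn{E_c} counts intra-community edges and \eqn{d_v} is node
#' degree. Strengths sum to the Newman modularity of the partition and may
#' be negative for weak communities; they are not clipped.
#'
#' @param partition a `community_partition`.
#' @param graph a `spatial_graph`.
#' @return length-C numeric vector of strengths.
#' @export
community_strength <- function(partition, graph) {
  m <- nrow(graph$edges)
  if (m == 0)
    stop("community strength is undefined on a graph with zero edges; ",
         "check the spatial graph construction")
  a <- partition$assignment
  if (length(a) != graph$n_spots)
    stop("partition does not cover the graph's spots")
  C <- partition$n_communities
  ci <- a[graph$edges[, 1]]
  cj <- a[graph$edges[, 2]]
  Ec <- vapply(seq_len(C) - 1L, function(c) sum(ci == c & cj == c),
               numeric(1))
  deg <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n_spots)
  degsum <- vapply(seq_len(C) - 1L, function(c) sum(deg[a == c]), numeric(1))
  Ec / m - degsum^2 / (4 * m^2)
}

#' Export a community partition
#'
#' @param partition a `community_partition`.
#' @param spot_ids per-spot identifiers.
#' @param tsv_path path for the spot-to-community TSV.
#' @param json_path optional path for a JSON of community strengths.
#' @return invisible `NULL`.
#' @export
export_partition <- function(partition, spot_ids, tsv_path,
                             json_path = NULL) {
  utils::write.table(
    data.frame(spot_id = spot_ids, community = partition$assignment),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(strengths = partition$strengths,
           n_communities = partition$n_communities),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
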