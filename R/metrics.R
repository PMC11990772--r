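#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
NULL

#' Normalized batch entropy of mixing
#'
#' For every spot, its region is its `k_region` nearest neighbors in the
#' embedding. The per-batch neighbor proportions are corrected for the
#' total batch sizes (so unequal slices score fairly), renormalized, and
#' their Shannon entropy computed; the score is the mean over spots divided
#' by `log(B)` so that perfect mixing scores 1 and perfect separation 0.
#'
#' @param Z n x h embedding matrix.
#' @param batch per-spot batch (slice) labels, at least 2 distinct.
#' @param k_region neighborhood size (default 30).
#' @return scalar in `[0, 1]`.
#' @export
batch_entropy <- function(Z, batch, k_region = 30) {
  Z <- as.matrix(Z)
  batch <- as.factor(batch)
  B <- nlevels(droplevels(batch))
  if (B < 2) stop("batch entropy needs at least 2 batches")
  batch <- droplevels(batch)
  n <- nrow(Z)
  k <- min(k_region, n - 1)
  idx <- knn_index(Z, k)
  P <- as.numeric(table(batch))
  bi <- as.integer(batch)
  ent <- vapply(seq_len(n), function(i) {
    region_entropy(tabulate(bi[idx[i, ]], nbins = B), P)
  }, numeric(1))
  mean(ent) / log(B)
}

# Size-corrected Shannon entropy of one region's batch composition.
region_entropy <- function(counts, batch_totals) {
  p <- counts / sum(counts)
  q <- p / batch_totals
  q <- q / sum(q)
  q <- q[q > 0]
  -sum(q * log(q))
}

#' Label and batch average silhouette widths
#'
#' Silhouettes are computed on the embedding (optionally its top principal
#' components). The label score rescales silhouettes to `[0, 1]`:
#' `cASW = mean((s + 1)/2)` — higher means better-separated biological
#' labels. The batch score uses the absolute silhouette,
#' `bASW = mean(1 - |s|)` — higher means better-mixed batches.
#'
#' @param Z n x h embedding.
#' @param labels per-spot biological labels (for cASW); `NULL` to skip.
#' @param batches per-spot batch labels (for bASW); `NULL` to skip.
#' @param use_pca project to the top `n_pcs` principal components first.
#' @param n_pcs number of components when `use_pca = TRUE`.
#' @return list with `cASW` and `bASW` (either may be `NULL`).
#' @export
silhouette_scores <- function(Z, labels = NULL, batches = NULL,
                              use_pca = FALSE, n_pcs = 20) {
  Z <- as.matrix(Z)
  if (use_pca) {
    n_pcs <- min(n_pcs, ncol(Z), nrow(Z) - 1)
    Z <- stats::prcomp(Z, rank. = n_pcs)$x
  }
  D <- stats::dist(Z)
  sil <- function(grp) {
    grp <- as.factor(droplevels(as.factor(grp)))
    if (nlevels(grp) < 2)
      stop("silhouette needs at least 2 categories")
    if (any(table(grp) == 1))
      warning("singleton category: its silhouette is set to 0",
              call. = FALSE)
    s <- cluster::silhouette(as.integer(grp), D)
    s[, "sil_width"]
  }
  out <- list(cASW = NULL, bASW = NULL)
  if (!is.null(labels)) out$cASW <- mean((sil(labels) + 1) / 2)
  if (!is.null(batches)) out$bASW <- mean(1 - abs(sil(batches)))
  out
}

# Per-spot inverse Simpson index over a perplexity-calibrated Gaussian
# neighborhood, as in the LISI family of metrics.
lisi_index <- function(Z, grp, perplexity = 30) {
  n <- nrow(Z)
  if (perplexity >= n)
    stop("perplexity must be smaller than the number of spots")
  grp <- as.integer(as.factor(grp))
  k <- min(n - 1, max(15, ceiling(3 * perplexity)))
  nn <- RANN::nn2(Z, Z, k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  d2 <- nn$nn.dists[, -1, drop = FALSE]^2
  target <- log(perplexity)
  vapply(seq_len(n), function(i) {
    di <- d2[i, ]
    # binary search the kernel precision to match the target entropy
    lo <- 1e-10; hi <- 1e10; beta <- 1
    for (it in 1:60) {
      w <- exp(-beta * di)
      sw <- sum(w)
      if (sw <= 0) { hi <- beta; beta <- (lo + hi) / 2; next }
      p <- w / sw
      Hcur <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(Hcur - target) < 1e-5) break
      if (Hcur > target) lo <- beta else hi <- beta
      beta <- (lo + hi) / 2
    }
    w <- exp(-beta * di)
    p <- w / sum(w)
    pc <- vapply(split(p, grp[idx[i, ]]), sum, numeric(1))
    1 / sum(pc^2)
  }, numeric(1))
}

#' LISI mixing and separation scores
#'
#' The local inverse Simpson index `x` measures the effective number of
#' categories in each spot's (perplexity-calibrated) neighborhood. Batch
#' mixing is rescaled to `[0, 1]` as `bLISI = median (x - 1)/(B - 1)`
#' (1 = perfect mixing) and label separation as
#' `cLISI = median (C - x)/(C - 1)` (1 = perfect separation), with `B`
#' batches and `C` label categories.
#'
#' @param Z n x h embedding.
#' @param labels per-spot labels (`NULL` to skip cLISI).
#' @param batches per-spot batches (`NULL` to skip bLISI).
#' @param perplexity neighborhood calibration (default 30).
#' @return list with `cLISI` and `bLISI`.
#' @export
lisi_scores <- function(Z, labels = NULL, batches = NULL, perplexity = 30) {
  Z <- as.matrix(Z)
  out <- list(cLISI = NULL, bLISI = NULL)
  if (!is.null(labels)) {
    C <- length(unique(labels))
    if (C < 2) stop("cLISI needs at least 2 label categories")
    x <- lisi_index(Z, labels, perplexity)
    out$cLISI <- stats::median((C - x) / (C - 1))
  }
  if (!is.null(batches)) {
    B <- length(unique(batches))
    if (B < 2) stop("bLISI needs at least 2 batches")
    x <- lisi_index(Z, batches, perplexity)
    out$bLISI <- stats::median((x - 1) / (B - 1))
  }
  out
}

#' Graph connectivity of labeled subgraphs
#'
#' Builds a symmetrized kNN graph on the embedding; for each label, the
#' subgraph restricted to that label's spots is scored by the fraction of
#' its spots in the largest connected component. The mean over labels is
#' returned — 1 when every label forms a single connected component.
#'
#' @param Z n x h embedding.
#' @param labels per-spot labels.
#' @param k_graph kNN size (default 15).
#' @return scalar in `(0, 1]`.
#' @export
graph_connectivity <- function(Z, labels, k_graph = 15) {
  Z <- as.matrix(Z)
  labels <- as.factor(labels)
  n <- nrow(Z)
  idx <- knn_index(Z, min(k_graph, n - 1))
  edges <- cbind(rep(seq_len(n), ncol(idx)), as.vector(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(igraph::add_vertices(g, max(0, n - igraph::vcount(g))))
  mean(vapply(levels(labels), function(l) {
    vs <- which(labels == l)
    sub <- igraph::induced_subgraph(g, vs)
    comp <- igraph::components(sub)
    max(comp$csize) / length(vs)
  }, numeric(1)))
}

#' Cluster an embedding into spatial domains
#'
#' Leiden or Louvain community detection on a kNN graph of the embedding,
#' or a Gaussian-mixture model (EM) with a fixed number of components —
#' the route recommended for Visium-like data.
#'
#' @param Z n x h embedding.
#' @param method `"leiden"`, `"louvain"` or `"gmm"`.
#' @param param Leiden/Louvain resolution, or the number of mixture
#'   components for `"gmm"`.
#' @param n_clusters for the graph methods, search the resolution (by
#'   bisection) until the partition has this many clusters, as is standard
#'   when the number of annotated domains is known; overrides `param`.
#' @param seed integer seed.
#' @param k_graph kNN size for the graph-based methods.
#' @return integer cluster label per spot.
#' @export
cluster_embeddings <- function(Z, method = c("leiden", "louvain", "gmm"),
                               param = 1.0, n_clusters = NULL, seed = 0,
                               k_graph = 15) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("embedding contains non-finite values")
  n <- nrow(Z)
  set.seed(seed)
  if (method == "gmm") {
    if (!is.null(n_clusters)) param <- n_clusters
    if (param > n) stop("more mixture components than spots")
    fit <- mclust::Mclust(Z, G = param, verbose = FALSE)
    return(as.integer(fit$classification))
  }
  idx <- knn_index(Z, min(k_graph, n - 1))
  edges <- cbind(rep(seq_len(n), ncol(idx)), as.vector(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(igraph::add_vertices(g, max(0, n - igraph::vcount(g))))
  run <- function(res) {
    set.seed(seed)
    cl <- if (method == "leiden")
      igraph::cluster_leiden(g, objective_function = "modularity",
                             resolution = res, n_iterations = 5)
    else igraph::cluster_louvain(g, resolution = res)
    as.integer(cl$membership)
  }
  if (is.null(n_clusters)) return(run(param))
  lo <- 0.01; hi <- 5
  memb <- run(hi)
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    memb <- run(mid)
    k <- length(unique(memb))
    if (k == n_clusters) break
    if (k < n_clusters) lo <- mid else hi <- mid
  }
  memb
}

#' Full integration-quality report
#'
#' Convenience wrapper computing every metric on a joint embedding.
#'
#' @param Z n x h joint embedding.
#' @param labels per-spot biological labels (optional).
#' @param batches per-spot batch labels.
#' @param k_region batch-entropy neighborhood size.
#' @param perplexity LISI perplexity.
#' @param k_graph graph-connectivity kNN size.
#' @return A `metric_report` list of scores and the parameters used.
#' @export
metric_report <- function(Z, labels = NULL, batches = NULL, k_region = 30,
                          perplexity = 30, k_graph = 15) {
  asw <- silhouette_scores(Z, labels, batches)
  lisi <- lisi_scores(Z, labels, batches, perplexity)
  structure(
    list(batch_entropy = if (!is.null(batches)) batch_entropy(Z, batches,
                                                              k_region),
         cASW = asw$cASW, bASW = asw$bASW,
         cLISI = lisi$cLISI, bLISI = lisi$bLISI,
         graph_connectivity = if (!is.null(labels))
           graph_connectivity(Z, labels, k_graph),
         params = list(k_region = k_region, perplexity = perplexity,
                       k_graph = k_graph)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (k in setdiff(names(x), "params")) {
    if (!is.null(x[[k]])) cat(sprintf("  %-18s %.4f\n", k, x[[k]]))
  }
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
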