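# Internal helpers shared across modules.

# Row-normalize to unit L2 norm with a small guard for zero rows.
l2_normalize_rows <- function(M, eps = 1e-8) {
  nrm <- sqrt(rowSums(M^2))
  M / pmax(nrm, eps)
}

# Min-max scale a numeric vector to [0, 1]; an all-equal vector maps to a
# constant 0.5 so downstream Bernoulli draws stay well defined.
minmax_norm <- function(x) {
  if (length(x) == 0) return(numeric(0))
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2])))
    return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Full pairwise Euclidean distance matrix via the Gram-matrix identity.
pairwise_dist <- function(Z) {
  sq <- rowSums(Z^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# k nearest neighbours among rows of `data` for each row of `query`
# (self excluded when data and query are the same matrix).
knn_index <- function(data, k, query = NULL) {
  self_query <- is.null(query)
  if (self_query) query <- data
  res <- RANN::nn2(data, query, k = min(k + self_query, nrow(data)))
  if (self_query) {
    idx <- res$nn.idx
    # drop the self column (first hit at distance 0); guard against exact ties
    out <- matrix(0L, nrow(idx), min(k, nrow(data) - 1))
    for (i in seq_len(nrow(idx))) {
      row <- idx[i, ]
      row <- row[row != i]
      out[i, ] <- row[seq_len(ncol(out))]
    }
    return(out)
  }
  res$nn.idx
}

# D^{-1/2}(A+I)D^{-1/2} assembled directly from a unique-pair edge list,
# avoiding intermediate sparse-matrix coercions in the training loop.
normalized_operator_edges <- function(edges, n) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n) + 1
  dinv <- 1 / sqrt(deg)
  w <- dinv[edges[, 1]] * dinv[edges[, 2]]
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2], seq_len(n)),
                       j = c(edges[, 2], edges[, 1], seq_len(n)),
                       x = c(w, w, dinv^2), dims = c(n, n))
}

adjacency_from_edges <- function(edges, n) {
  if (nrow(edges) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  A@x[] <- 1  # collapse duplicate triplets to 0/1
  A
}
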