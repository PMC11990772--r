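#' Initialize encoder parameters
#'
#' Two-layer graph-convolutional encoder: the first layer maps the `m`
#' input genes to `2h` dimensions followed by a PReLU activation with a
#' single learnable slope, the second layer maps to the `h`-dimensional
#' embedding. Weights are Glorot-uniform initialized.
#'
#' @param m input feature (gene) count.
#' @param h embedding dimension (default 50).
#' @param prelu_slope initial PReLU negative-side slope.
#' @return An `encoder_params` list: `W1`, `b1`, `a` (PReLU slope), `W2`,
#'   `b2`, `h`, `m`.
#' @export
init_encoder <- function(m, h = 50, prelu_slope = 0.25) {
  stopifnot(h >= 2, m >= 1)
  glorot <- function(fin, fout) {
    lim <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
  }
  structure(
    list(W1 = glorot(m, 2 * h), b1 = rep(0, 2 * h), a = prelu_slope,
         W2 = glorot(2 * h, h), b2 = rep(0, h), h = h, m = m),
    class = "encoder_params"
  )
}

prelu <- function(x, a) {
  neg <- x < 0
  x + (a - 1) * (x * neg)
}

encoder_forward <- function(X, Ahat, params) {
  H1 <- as.matrix(Ahat %*% (X %*% params$W1))
  H1 <- sweep(H1, 2, params$b1, "+")
  A1 <- prelu(H1, params$a)
  Z <- as.matrix(Ahat %*% (A1 %*% params$W2))
  Z <- sweep(Z, 2, params$b2, "+")
  list(Z = Z, H1 = H1, A1 = A1, X = X, Ahat = Ahat)
}

# Gradients of the encoder parameters given dL/dZ and the forward cache.
encoder_backward <- function(dZ, cache, params) {
  G2 <- as.matrix(cache$Ahat %*% dZ)          # Ahat symmetric
  dW2 <- crossprod(cache$A1, G2)
  db2 <- colSums(dZ)
  dA1 <- G2 %*% t(params$W2)
  neg <- cache$H1 < 0
  dH1 <- dA1 + (params$a - 1) * (dA1 * neg)
  da <- sum(dA1 * cache$H1 * neg)
  G1 <- as.matrix(cache$Ahat %*% dH1)
  dW1 <- crossprod(cache$X, G1)
  db1 <- colSums(dH1)
  list(W1 = dW1, b1 = db1, a = da, W2 = dW2, b2 = db2)
}

#' Encode a (possibly augmented) graph view
#'
#' Computes \eqn{Z = \hat A \, \mathrm{PReLU}(\hat A X W_1 + b_1) W_2 + b_2}
#' where \eqn{\hat A} is the symmetric degree-normalized adjacency (with
#' self-loops) of the view's graph. Deterministic given parameters and
#' inputs.
#'
#' @param view an `augmented_view`, or a plain n x m matrix.
#' @param params `encoder_params` from [init_encoder()].
#' @param adjacency adjacency matrix (0/1) when `view` is a plain matrix;
#'   ignored otherwise.
#' @return n x h embedding matrix.
#' @export
encode <- function(view, params, adjacency = NULL) {
  if (inherits(view, "augmented_view")) {
    X <- view$X_masked
    A <- view$adjacency_masked
  } else {
    X <- as.matrix(view)
    if (is.null(adjacency)) stop("plain-matrix input needs an adjacency")
    A <- adjacency
  }
  if (ncol(X) != nrow(params$W1))
    stop("shape error: input has ", ncol(X), " features but encoder expects ",
         nrow(params$W1))
  encoder_forward(X, normalize_adjacency(A), params)$Z
}

# Normalize rows and compute the chain-rule factor back to Z.
normalize_with_grad <- function(Z, eps = 1e-8) {
  nrm <- pmax(sqrt(rowSums(Z^2)), eps)
  list(U = Z / nrm, nrm = nrm)
}

backprop_normalize <- function(dU, U, nrm) {
  (dU - rowSums(dU * U) * U) / nrm
}

#' InfoNCE contrastive loss between two views
#'
#' Symmetrized InfoNCE over cosine similarities at temperature `tau`: each
#' spot's embedding in one view is contrasted against its own embedding in
#' the other view (positive) versus all other spots in both views
#' (negatives). The mean of the two view directions is returned.
#'
#' @param Z1,Z2 n x h embedding matrices of the two views.
#' @param tau temperature (> 0).
#' @return nonnegative scalar loss.
#' @export
infonce_loss <- function(Z1, Z2, tau = 0.02) {
  community_infonce_loss(Z1, Z2, partition = NULL, tau = tau, gamma = 0)
}

#' Community-enhanced InfoNCE loss
#'
#' InfoNCE with a community bonus added to every similarity term:
#' \eqn{\tilde s_{ij} = s_{ij} + \gamma (H_{i:} + H_{j:}) S}, so pairs in
#' strong communities are treated as softer negatives. With `gamma = 0`
#' this reduces exactly to [infonce_loss()]; with a single community the
#' constant bonus cancels in the softmax.
#'
#' @param Z1,Z2 n x h embeddings of the two views.
#' @param partition a `community_partition` with strengths (or `NULL`).
#' @param tau temperature.
#' @param gamma bonus coefficient (see [gamma_schedule()]).
#' @return scalar loss.
#' @export
community_infonce_loss <- function(Z1, Z2, partition, tau = 0.02,
                                   gamma = 0) {
  stopifnot(all(dim(Z1) == dim(Z2)), tau > 0)
  if (nrow(Z1) == 0) stop("empty-input error: no embeddings")
  b <- infonce_bonus(partition, gamma, nrow(Z1))
  U1 <- l2_normalize_rows(as.matrix(Z1))
  U2 <- l2_normalize_rows(as.matrix(Z2))
  cpp_infonce(U1, U2, tau, b, FALSE)$loss
}

infonce_bonus <- function(partition, gamma, n) {
  if (is.null(partition) || gamma == 0) return(numeric(0))
  stopifnot(length(partition$assignment) == n)
  gamma * as.vector(partition$H %*% partition$strengths)
}

# Loss + gradients wrt Z1, Z2 (training path).
infonce_grad <- function(Z1, Z2, tau, partition = NULL, gamma = 0) {
  b <- infonce_bonus(partition, gamma, nrow(Z1))
  n1 <- normalize_with_grad(Z1)
  n2 <- normalize_with_grad(Z2)
  res <- cpp_infonce(n1$U, n2$U, tau, b, TRUE, single = TRUE)
  list(loss = res$loss,
       dZ1 = backprop_normalize(res$dU1, n1$U, n1$nrm),
       dZ2 = backprop_normalize(res$dU2, n2$U, n2$nrm))
}

#' Dynamic community-bonus schedule
#'
#' \eqn{\gamma_k = \min(\max(0, k - k_0), \gamma_{max})}: zero until epoch
#' `k0`, then increasing to a ceiling of `gamma_max`.
#'
#' @param k current epoch (>= 0).
#' @param k0 warm-up epoch count.
#' @param gamma_max ceiling.
#' @return scalar gamma.
#' @export
gamma_schedule <- function(k, k0, gamma_max) {
  min(max(0, k - k0), gamma_max)
}

#' Spatial similarity constraint within one slice
#'
#' Penalizes embedding similarity between spatially distant spots:
#' \eqn{L = \sum_{ij} D^s_{ij}(1 - D^Z_{ij}) / n^2} with both the spatial
#' and embedding distance matrices scaled to `[0, 1]` over the evaluated
#' pairs. Above `sample_pairs` spots a seeded random subset of pairs is
#' averaged instead of the full double sum.
#'
#' @param Z n x h embeddings.
#' @param coords n x 2 spatial coordinates.
#' @param sample_pairs optional number of random pairs to subsample.
#' @return scalar loss.
#' @export
within_slice_loss <- function(Z, coords, sample_pairs = NULL) {
  Z <- as.matrix(Z)
  coords <- as.matrix(coords)
  stopifnot(nrow(Z) == nrow(coords))
  n <- nrow(Z)
  if (n < 2) {
    warning("within-slice loss needs at least 2 spots; returning 0",
            call. = FALSE)
    return(0)
  }
  if (!is.null(sample_pairs)) {
    i <- sample.int(n, sample_pairs, replace = TRUE)
    j <- sample.int(n, sample_pairs, replace = TRUE)
    ok <- i != j
    i <- i[ok]; j <- j[ok]
    ds <- sqrt(rowSums((coords[i, , drop = FALSE] -
                          coords[j, , drop = FALSE])^2))
    dz <- sqrt(rowSums((Z[i, , drop = FALSE] - Z[j, , drop = FALSE])^2))
    return(mean(minmax_norm(ds) * (1 - minmax_norm(dz))))
  }
  Dsn <- normalized_spatial_dist(coords)
  cpp_within(Z, Dsn, FALSE)$loss
}

normalized_spatial_dist <- function(coords) {
  Ds <- pairwise_dist(as.matrix(coords))
  mx <- max(Ds)
  if (mx > 0) Ds / mx else Ds
}
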