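#' Mutual nearest neighbor pairs between two slices' embeddings
#'
#' A pair `(i, j)` is reported when spot `j` of the second slice is among
#' the `k_mnn` Euclidean nearest neighbors of spot `i` of the first slice
#' AND vice versa. MNN pairs serve as cross-slice alignment anchors.
#'
#' @param Z_a,Z_b embedding matrices (rows = spots) with a shared dimension.
#' @param k_mnn neighborhood size (default 5).
#' @return integer matrix with columns `a`, `b` (one row per pair).
#' @export
find_mnn_pairs <- function(Z_a, Z_b, k_mnn = 5) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  if (nrow(Z_a) == 0 || nrow(Z_b) == 0)
    stop("empty-input error: both slices need at least one spot")
  stopifnot(ncol(Z_a) == ncol(Z_b))
  ka <- min(k_mnn, nrow(Z_b))
  kb <- min(k_mnn, nrow(Z_a))
  nb_of_a <- RANN::nn2(Z_b, Z_a, k = ka)$nn.idx   # rows: a -> neighbors in b
  na_of_b <- RANN::nn2(Z_a, Z_b, k = kb)$nn.idx   # rows: b -> neighbors in a
  cand_a <- rep(seq_len(nrow(Z_a)), each = ka)
  cand_b <- as.vector(t(nb_of_a))
  mutual <- vapply(seq_along(cand_a), function(t) {
    cand_a[t] %in% na_of_b[cand_b[t], ]
  }, logical(1))
  cbind(a = cand_a[mutual], b = cand_b[mutual])
}

#' Sample alignment triplets from MNN pairs
#'
#' Each MNN pair becomes one triplet: the first-slice spot is the anchor,
#' its mutual neighbor in the other slice the positive, and the negative is
#' drawn uniformly from the anchor's slice excluding the anchor itself.
#'
#' @param pairs 2-column matrix of MNN pairs (`a`, `b`).
#' @param n_a number of spots in the anchor slice.
#' @return A `triplet_set`: `anchors`, `positives`, `negatives`,
#'   `n_triplets`.
#' @export
sample_triplets <- function(pairs, n_a) {
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("empty-input error: no MNN pairs to sample triplets from")
  if (n_a < 2) {
    warning("anchor slice has a single spot; no negatives can be sampled",
            call. = FALSE)
    return(structure(list(anchors = integer(0), positives = integer(0),
                          negatives = integer(0), n_triplets = 0L),
                     class = "triplet_set"))
  }
  anchors <- pairs[, 1]
  negatives <- vapply(anchors, function(a) {
    repeat {
      cand <- sample.int(n_a, 1)
      if (cand != a) return(cand)
    }
  }, integer(1))
  structure(
    list(anchors = as.integer(anchors), positives = as.integer(pairs[, 2]),
         negatives = negatives, n_triplets = nrow(pairs)),
    class = "triplet_set"
  )
}

#' Triplet alignment loss
#'
#' Mean hinge over triplets:
#' \eqn{\max(\|Z_a - Z_p\|^2 - \|Z_a - Z_n\|^2 + \theta, 0)}, pulling each
#' anchor within margin `theta` of its cross-slice positive relative to the
#' within-slice negative.
#'
#' @param Z_anchor_slice embeddings of the anchor (and negative) slice.
#' @param Z_positive_slice embeddings of the positive slice.
#' @param triplets a `triplet_set`.
#' @param theta margin (default 1.0).
#' @return nonnegative scalar loss.
#' @export
triplet_loss <- function(Z_anchor_slice, Z_positive_slice, triplets,
                         theta = 1.0) {
  triplet_grad(Z_anchor_slice, Z_positive_slice, triplets, theta,
               grad = FALSE)$loss
}

triplet_grad <- function(Za, Zp, tri, theta = 1.0, grad = TRUE) {
  Za <- as.matrix(Za); Zp <- as.matrix(Zp)
  if (tri$n_triplets == 0) {
    warning("empty triplet set; loss is 0", call. = FALSE)
    out <- list(loss = 0)
    if (grad) {
      out$dZa <- matrix(0, nrow(Za), ncol(Za))
      out$dZp <- matrix(0, nrow(Zp), ncol(Zp))
    }
    return(out)
  }
  A <- Za[tri$anchors, , drop = FALSE]
  P <- Zp[tri$positives, , drop = FALSE]
  N <- Za[tri$negatives, , drop = FALSE]
  dp2 <- rowSums((A - P)^2)
  dn2 <- rowSums((A - N)^2)
  marg <- dp2 - dn2 + theta
  active <- marg > 0
  loss <- sum(pmax(marg, 0)) / tri$n_triplets
  out <- list(loss = loss)
  if (!grad) return(out)
  dZa <- matrix(0, nrow(Za), ncol(Za))
  dZp <- matrix(0, nrow(Zp), ncol(Zp))
  if (any(active)) {
    sc <- 2 / tri$n_triplets
    ai <- tri$anchors[active]; pi <- tri$positives[active]
    ni <- tri$negatives[active]
    gA <- sc * (N[active, , drop = FALSE] - P[active, , drop = FALSE])
    gP <- sc * (P[active, , drop = FALSE] - A[active, , drop = FALSE])
    gN <- sc * (A[active, , drop = FALSE] - N[active, , drop = FALSE])
    for (t in seq_along(ai)) {
      dZa[ai[t], ] <- dZa[ai[t], ] + gA[t, ]
      dZp[pi[t], ] <- dZp[pi[t], ] + gP[t, ]
      dZa[ni[t], ] <- dZa[ni[t], ] + gN[t, ]
    }
  }
  out$dZa <- dZa
  out$dZp <- dZp
  out
}
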