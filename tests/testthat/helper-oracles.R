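# Independent oracles and small fixtures used across the suite. These are
# deliberately naive implementations (loops, enumeration) kept separate from
# the package's vectorized/compiled paths.

# Naive symmetrized InfoNCE with optional per-spot bonus vector b
# (pair bonus b_i + b_j added to every similarity term).
naive_infonce <- function(Z1, Z2, tau, b = NULL) {
  n <- nrow(Z1)
  U1 <- Z1 / sqrt(rowSums(Z1^2))
  U2 <- Z2 / sqrt(rowSums(Z2^2))
  s11 <- tcrossprod(U1) / tau
  s22 <- tcrossprod(U2) / tau
  s12 <- (U1 %*% t(U2)) / tau
  if (!is.null(b)) {
    B <- outer(b, b, "+")
    s11 <- s11 + B; s22 <- s22 + B; s12 <- s12 + B
  }
  dir_loss <- function(intra, cross) {
    tot <- 0
    for (i in seq_len(n)) {
      den <- sum(exp(intra[i, -i])) + sum(exp(cross[i, ]))
      tot <- tot - cross[i, i] + log(den)
    }
    tot / n
  }
  (dir_loss(s11, s12) + dir_loss(s22, t(s12))) / 2
}

# Brute-force Delaunay edges by empty-circumcircle enumeration over all
# triangles, vectorized over triangles. Assumes points in general position
# (random coordinates).
brute_delaunay_edges <- function(coords, tol = 1e-9) {
  n <- nrow(coords)
  tri <- t(utils::combn(n, 3))
  ax <- coords[tri[, 1], 1]; ay <- coords[tri[, 1], 2]
  bx <- coords[tri[, 2], 1]; by <- coords[tri[, 2], 2]
  cx <- coords[tri[, 3], 1]; cy <- coords[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ok <- abs(d) > 1e-12
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  # squared distance of every point to every circumcenter
  dx <- outer(ux, coords[, 1], "-")
  dy <- outer(uy, coords[, 2], "-")
  inside <- (dx^2 + dy^2) < (r2 - tol)
  inside[cbind(seq_len(nrow(tri)), tri[, 1])] <- FALSE
  inside[cbind(seq_len(nrow(tri)), tri[, 2])] <- FALSE
  inside[cbind(seq_len(nrow(tri)), tri[, 3])] <- FALSE
  empty <- ok & !apply(inside, 1, any)
  e <- rbind(tri[empty, c(1, 2), drop = FALSE],
             tri[empty, c(1, 3), drop = FALSE],
             tri[empty, c(2, 3), drop = FALSE])
  unique(t(apply(e, 1, sort)))
}

# Alpha-graph oracle: brute-force Delaunay + closed length threshold.
brute_alpha_edges <- function(coords, k) {
  r <- estimate_radius(coords, k)
  e <- brute_delaunay_edges(coords)
  len <- sqrt(rowSums((coords[e[, 1], , drop = FALSE] -
                         coords[e[, 2], , drop = FALSE])^2))
  e[len <= 2 * r, , drop = FALSE]
}

edge_key <- function(edges) {
  if (nrow(edges) == 0) return(character(0))
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "-"))
}

# Two triangles {1,2,3} and {4,5,6} joined by the bridge edge 3-4.
bridge_graph <- function() {
  coords <- rbind(c(0, 0), c(1, 0), c(0.5, 0.9),
                  c(3, 0.45), c(4, 0), c(4, 1))
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4))
  structure(list(n_spots = 6L, edges = edges,
                 lengths = sqrt(rowSums((coords[edges[, 1], ] -
                                           coords[edges[, 2], ])^2)),
                 adjacency = spotglue:::adjacency_from_edges(edges, 6),
                 radius = 1, k_neighbors = 2, fallback = FALSE),
            class = "spatial_graph")
}

bridge_partition <- function(graph = bridge_graph()) {
  part <- spotglue:::partition_from_assignment(c(0L, 0L, 0L, 1L, 1L, 1L))
  part$strengths <- community_strength(part, graph)
  part
}

# Small two-slice simulation for fast end-to-end tests.
tiny_sim <- function(seed = 11, n_genes = 80, nx = 10, ny = 8) {
  cfg <- sim_config(n_domains = 3,
                    extents = list(c(nx, ny), c(nx, ny)),
                    spacings = c(1, 1), n_genes = n_genes,
                    n_markers_per_domain = 8, seed = seed)
  simulate_slices(cfg)
}

preprocessed_pair <- function(sim) {
  sl <- lapply(sim$slices, preprocess)
  select_shared_hvgs(sl, n_top = 3000, raw_slices = sim$slices)$slices
}
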