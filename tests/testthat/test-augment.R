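test_that("attribute weights follow the voting formula and its tie rule", {
  part <- spotglue:::partition_from_assignment(c(0L, 1L))
  part$strengths <- c(0.3, 0.1)
  # X = I2 with one spot per community: raw scores (0.3, 0.1) -> (1, 0)
  expect_equal(attribute_mask_weights(diag(2), part), c(1, 0))
  # all-zero X -> all-equal raw scores -> constant 0.5
  expect_equal(attribute_mask_weights(matrix(0, 2, 3), part), rep(0.5, 3))
  # min-max is invariant to positive rescaling of the strengths
  part2 <- part; part2$strengths <- part$strengths * 37
  set.seed(1); X <- matrix(rexp(8), 2, 4)
  expect_equal(attribute_mask_weights(X, part),
               attribute_mask_weights(X, part2))
})

test_that("edge weights separate intra- from inter-community edges", {
  g <- bridge_graph()
  part <- bridge_partition(g)
  w <- edge_mask_weights(g, part)
  # intra edges (strength 5/28) normalize to 1, the bridge to 0
  expect_equal(w, c(rep(1, 6), 0))
  # single community: all edges tie at 0.5
  p1 <- spotglue:::partition_from_assignment(rep(0L, 6))
  p1$strengths <- community_strength(p1, g)
  expect_equal(edge_mask_weights(g, p1), rep(0.5, 7))
})

test_that("inter-community edges never outrank the strongest intra edges", {
  g <- bridge_graph()
  part <- bridge_partition(g)
  w <- edge_mask_weights(g, part)
  intra0 <- part$assignment[g$edges[, 1]] == part$assignment[g$edges[, 2]]
  expect_lte(max(w[!intra0]), max(w[intra0]))
  for (seed in 1:12) {
    set.seed(seed)
    n <- 14
    gi <- igraph::sample_gnp(n, 0.3)
    if (igraph::ecount(gi) < 3) next
    edges <- igraph::as_edgelist(gi)
    graph <- structure(list(n_spots = n, edges = edges,
                            adjacency = spotglue:::adjacency_from_edges(edges, n)),
                       class = "spatial_graph")
    a <- as.integer(factor(sample(0:2, n, TRUE))) - 1L
    part <- spotglue:::partition_from_assignment(a)
    part$strengths <- community_strength(part, graph)
    # the sign structure argument requires nonnegative strengths, as for
    # partitions found by modularity optimization
    if (any(part$strengths < 0)) next
    w <- edge_mask_weights(graph, part)
    intra <- a[edges[, 1]] == a[edges[, 2]]
    if (any(intra) && any(!intra))
      expect_lte(max(w[!intra]), max(w[intra]) + 1e-12)
  }
})

test_that("degenerate masking probabilities give identity or empty views", {
  g <- bridge_graph()
  part <- bridge_partition(g)
  set.seed(1); X <- matrix(rexp(6 * 4), 6, 4)
  v0 <- sample_view(X, g, part, p_attr = 0, p_edge = 1, edge_keep_floor = 1)
  expect_equal(v0$X_masked, X, ignore_attr = TRUE)
  expect_equal(as.matrix(v0$adjacency_masked), as.matrix(g$adjacency))
  r0 <- random_view(X, g, p_attr = 0, p_edge_drop = 0)
  expect_equal(r0$X_masked, X, ignore_attr = TRUE)
  r1 <- random_view(X, g, p_attr = 0, p_edge_drop = 1)
  expect_equal(sum(r1$adjacency_masked), 0)
})

test_that("views only remove structure and mask whole gene columns", {
  sim <- tiny_sim()
  s <- preprocessed_pair(sim)[[1]]
  g <- build_spatial_graph(s$coords, 6)
  part <- detect_communities(s, g, "expression", seed = 2)
  set.seed(3)
  v <- sample_view(s$X, g, part, 0.5, 0.7)
  expect_equal(v$X_masked, s$X * v$attr_mask, ignore_attr = TRUE)
  # column-constant mask
  expect_true(all(apply(v$attr_mask, 2, function(col) length(unique(col))) == 1))
  # no new adjacency entries
  expect_true(all((v$adjacency_masked - g$adjacency) <= 0))
  expect_true(Matrix::isSymmetric(v$adjacency_masked))
  # same seed -> identical view
  set.seed(99); a <- sample_view(s$X, g, part, 0.4, 0.8)
  set.seed(99); b <- sample_view(s$X, g, part, 0.4, 0.8)
  expect_identical(a$attr_mask, b$attr_mask)
  expect_identical(a$edge_mask, b$edge_mask)
})

test_that("empirical keep rates match the Bernoulli model", {
  # all-equal weights tie at w = 0.5; keep prob = 1 - 0.5 * 0.6 = 0.7
  part <- spotglue:::partition_from_assignment(c(0L, 1L))
  part$strengths <- c(0.2, 0.1)
  X <- matrix(0, 2, 10000)
  g <- structure(list(n_spots = 2L, edges = cbind(1L, 2L),
                      adjacency = spotglue:::adjacency_from_edges(cbind(1L, 2L), 2)),
                 class = "spatial_graph")
  set.seed(4)
  v <- sample_view(X, g, part, p_attr = 0.6, p_edge = 1)
  keep <- mean(v$attr_mask[1, ])
  sigma <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(keep - 0.7), 3 * sigma)
  # uniform random masking matches its rate too
  set.seed(5)
  r <- random_view(X, g, p_attr = 0.25, p_edge_drop = 0)
  expect_lt(abs(mean(1 - r$attr_mask[1, ]) - 0.25),
            3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("higher masking weight lowers the expected keep probability", {
  part <- spotglue:::partition_from_assignment(c(0L, 1L))
  part$strengths <- c(0.4, 0.1)
  X <- diag(2)  # weights (1, 0)
  w <- attribute_mask_weights(X, part)
  keepp <- 1 - w * 0.5
  expect_true(keepp[1] < keepp[2])
})
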