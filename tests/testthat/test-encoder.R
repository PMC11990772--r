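test_that("encoder forward matches hand-computed propagation", {
  # 2-node graph with one edge: Ahat is the all-0.5 matrix
  p <- structure(list(W1 = matrix(c(0.1, -0.2, 0.3, 0.05), 2, 2),
                      b1 = c(0.01, -0.02), a = 0.25,
                      W2 = matrix(c(0.5, -0.4, 0.2, 0.1), 2, 2),
                      b2 = c(0, 0.1), h = 2, m = 2),
                 class = "encoder_params")
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  X <- diag(2)
  Ahat <- matrix(0.5, 2, 2)
  H1 <- Ahat %*% X %*% p$W1 + matrix(p$b1, 2, 2, byrow = TRUE)
  A1 <- ifelse(H1 > 0, H1, p$a * H1)
  Zexp <- Ahat %*% A1 %*% p$W2 + matrix(p$b2, 2, 2, byrow = TRUE)
  expect_equal(encode(X, p, adjacency = A), as.matrix(Zexp),
               tolerance = 1e-12)
  # zero weights propagate to zero embeddings
  p0 <- p; p0$W1[] <- 0; p0$b1[] <- 0; p0$W2[] <- 0; p0$b2[] <- 0
  expect_equal(encode(X, p0, adjacency = A), matrix(0, 2, 2))
  expect_error(encode(matrix(0, 2, 5), p, adjacency = A), "shape error")
})

test_that("an isolated node's embedding depends only on its own features", {
  set.seed(1)
  p <- init_encoder(4, h = 3)
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(3, 3))
  X1 <- matrix(rnorm(12), 3, 4)
  X2 <- X1; X2[1:2, ] <- rnorm(8)  # perturb only the connected pair
  Z1 <- encode(X1, p, adjacency = A)
  Z2 <- encode(X2, p, adjacency = A)
  expect_equal(Z1[3, ], Z2[3, ])
})

test_that("encoding is permutation-equivariant", {
  set.seed(2)
  n <- 25
  co <- cbind(runif(n), runif(n))
  g <- build_spatial_graph(co, 4)
  X <- matrix(rnorm(n * 6), n, 6)
  p <- init_encoder(6, h = 4)
  Z <- encode(X, p, adjacency = g$adjacency)
  perm <- sample(n)
  Aperm <- g$adjacency[perm, perm]
  Zp <- encode(X[perm, ], p, adjacency = Aperm)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10)
})

test_that("InfoNCE hand cases and reductions hold", {
  set.seed(3)
  Za <- matrix(rnorm(6), 1, 6)
  expect_equal(infonce_loss(Za, Za, tau = 0.5), 0)
  # n = 2, all four embeddings identical -> log 3 at any temperature
  Zb <- Za[c(1, 1), , drop = FALSE]
  expect_equal(infonce_loss(Zb, Zb, tau = 0.5), log(3), tolerance = 1e-9)
  expect_equal(infonce_loss(Zb, Zb, tau = 1.7), log(3), tolerance = 1e-9)
  expect_error(infonce_loss(Zb[0, , drop = FALSE], Zb[0, , drop = FALSE]),
               "empty-input")
})

test_that("vectorized InfoNCE equals the naive double-loop oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:12, 1)
    Z1 <- matrix(rnorm(n * 7), n, 7)
    Z2 <- matrix(rnorm(n * 7), n, 7)
    expect_equal(infonce_loss(Z1, Z2, tau = 0.5),
                 naive_infonce(Z1, Z2, 0.5), tolerance = 1e-9)
    # community-enhanced version against the same oracle with bonuses
    a <- as.integer(factor(sample(0:2, n, TRUE))) - 1L
    part <- spotglue:::partition_from_assignment(a)
    part$strengths <- runif(part$n_communities, -0.2, 0.4)
    b <- 0.8 * as.vector(part$H %*% part$strengths)
    expect_equal(community_infonce_loss(Z1, Z2, part, 0.5, gamma = 0.8),
                 naive_infonce(Z1, Z2, 0.5, b), tolerance = 1e-9)
  }
})

test_that("community bonus reductions: gamma 0 and constant bonuses cancel", {
  set.seed(4)
  Z1 <- matrix(rnorm(40), 8, 5); Z2 <- matrix(rnorm(40), 8, 5)
  part <- spotglue:::partition_from_assignment(rep(0L, 8))
  part$strengths <- 0.37
  expect_equal(community_infonce_loss(Z1, Z2, part, 0.5, gamma = 0),
               infonce_loss(Z1, Z2, 0.5), tolerance = 1e-12)
  # single community: the constant pairwise bonus cancels in the softmax
  expect_equal(community_infonce_loss(Z1, Z2, part, 0.5, gamma = 2.3),
               infonce_loss(Z1, Z2, 0.5), tolerance = 1e-7)
  # shift invariance of strengths under a single community
  p2 <- part; p2$strengths <- part$strengths + 5
  expect_equal(community_infonce_loss(Z1, Z2, p2, 0.5, gamma = 1),
               community_infonce_loss(Z1, Z2, part, 0.5, gamma = 1),
               tolerance = 1e-6)
  expect_gte(infonce_loss(Z1, Z2, 0.5), 0)
})

test_that("gamma schedule is a clipped ramp", {
  expect_equal(gamma_schedule(100, 100, 1), 0)
  expect_equal(gamma_schedule(50, 100, 1), 0)
  expect_equal(gamma_schedule(150, 100, 1.0), 1.0)
  expect_equal(gamma_schedule(101, 100, 5), 1)
})

test_that("within-slice loss matches hand-evaluated cases", {
  # identical embeddings, two spots: L = (1 + 1)/4
  expect_equal(within_slice_loss(matrix(1, 2, 3),
                                 rbind(c(0, 0), c(2, 0))), 0.5)
  # all spots at one coordinate: spatial distances vanish
  expect_equal(within_slice_loss(matrix(rnorm(9), 3, 3),
                                 matrix(1, 3, 2)), 0)
  # three equally spaced collinear spots with proportional embeddings:
  # normalized Ds == Dz, L = sum Ds(1 - Ds)/9 = 1/9
  co <- cbind(c(0, 1, 2), 0)
  Z <- cbind(c(0, 5, 10), 0, 0)
  expect_equal(within_slice_loss(Z, co), 1 / 9, tolerance = 1e-12)
  expect_warning(w1 <- within_slice_loss(matrix(1, 1, 3), matrix(0, 1, 2)),
                 "at least 2")
  expect_equal(w1, 0)
})

test_that("within-slice loss rewards matching the spatial layout", {
  set.seed(6)
  co <- cbind(runif(40), runif(40))
  good <- cbind(co, matrix(0, 40, 3))          # embeds the layout itself
  bad <- good[sample(40), ]                    # scrambled assignment
  expect_lt(within_slice_loss(good, co), within_slice_loss(bad, co))
  # subsampled evaluation approximates the full loss
  set.seed(7)
  full <- within_slice_loss(good, co)
  sub <- within_slice_loss(good, co, sample_pairs = 30000)
  expect_lt(abs(full - sub), 0.05)
})
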