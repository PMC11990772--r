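# Two far-separated Gaussian blobs with interleaved batches: labels are
# perfectly separated, batches perfectly mixed.
blob_fixture <- function(n_per = 60, sep = 50, seed = 1) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  list(Z = Z,
       labels = rep(c("A", "B"), each = n_per),
       batches = rep(c("x", "y"), n_per))  # interleaved within blobs
}

test_that("batch entropy reaches its analytic extremes", {
  f <- blob_fixture()
  expect_gt(batch_entropy(f$Z, f$batches, k_region = 15), 0.95)
  # batches fully separated in space -> entropy 0
  sepb <- rep(c("x", "y"), each = 60)
  expect_lt(batch_entropy(f$Z, sepb, k_region = 15), 1e-6)
  expect_error(batch_entropy(f$Z, rep("x", 120)), "2 batches")
})

test_that("region entropy matches the weighted hand case", {
  # 3 spots of batch A (P = 100), 1 of batch B (P = 50):
  # corrected proportions (0.6, 0.4)
  e <- spotglue:::region_entropy(c(3, 1), c(100, 50))
  expect_equal(e, -(0.6 * log(0.6) + 0.4 * log(0.4)), tolerance = 1e-12)
  expect_equal(e, 0.6730117, tolerance = 1e-6)
  expect_equal(e / log(2), 0.9709506, tolerance = 1e-6)
  # pure region -> zero entropy
  expect_equal(spotglue:::region_entropy(c(4, 0), c(100, 50)), 0)
})

test_that("batch-size correction is invariant to duplicating a batch", {
  expect_equal(spotglue:::region_entropy(c(3, 1), c(100, 50)),
               spotglue:::region_entropy(c(6, 2), c(200, 100)))
  # doubling one batch's totals changes the correction as designed
  expect_false(isTRUE(all.equal(
    spotglue:::region_entropy(c(3, 1), c(100, 50)),
    spotglue:::region_entropy(c(3, 1), c(100, 100)))))
})

test_that("silhouette scores hit their extremes on constructed fixtures", {
  f <- blob_fixture()
  s <- silhouette_scores(f$Z, labels = f$labels, batches = f$batches)
  expect_gt(s$cASW, 0.95)   # tight, far-separated label clusters
  expect_gt(s$bASW, 0.9)    # identically interleaved batches
  sep <- silhouette_scores(f$Z, batches = rep(c("x", "y"), each = 60))
  expect_lt(sep$bASW, 0.05) # perfectly separated batches
  expect_error(silhouette_scores(f$Z, labels = rep("A", 120)), "2 categories")
  expect_warning(
    silhouette_scores(f$Z, labels = c("solo", f$labels[-1])), "singleton")
})

test_that("LISI rescaling reaches 0/1 on perfect mixing and separation", {
  f <- blob_fixture(n_per = 80)
  l <- lisi_scores(f$Z, labels = f$labels, batches = f$batches,
                   perplexity = 20)
  expect_gt(l$bLISI, 0.9)   # mixed batches: x -> B
  expect_gt(l$cLISI, 0.9)   # separated labels: x -> 1
  sep <- lisi_scores(f$Z, batches = rep(c("x", "y"), each = 80),
                     perplexity = 20)
  expect_lt(sep$bLISI, 0.1)
  expect_error(lisi_scores(f$Z, batches = f$batches, perplexity = 200),
               "perplexity")
})

test_that("graph connectivity equals the component-enumeration oracle", {
  f <- blob_fixture()
  # one connected blob under one label scores exactly 1
  one <- matrix(rnorm(80), 40, 2)
  expect_equal(graph_connectivity(one, rep("A", 40), k_graph = 10), 1.0)
  expect_gt(graph_connectivity(f$Z, f$labels, k_graph = 10), 0.99)
  # label split into two spatially separated groups of 8 and 2 scores 0.8
  set.seed(2)
  Z <- rbind(matrix(rnorm(16, 0, 0.1), 8, 2),
             matrix(rnorm(4, 40, 0.1), 2, 2),
             matrix(rnorm(20, 60, 0.1), 10, 2))
  labs <- rep(c("p", "q"), c(10, 10))
  gc <- graph_connectivity(Z, labs, k_graph = 3)
  expect_equal(gc, mean(c(0.8, 1.0)))
  # brute-force oracle on random data
  for (seed in 1:4) {
    set.seed(seed)
    Zr <- matrix(rnorm(60), 30, 2)
    lr <- sample(c("a", "b"), 30, TRUE)
    k <- 4
    idx <- spotglue:::knn_index(Zr, k)
    oracle <- mean(vapply(unique(lr), function(l) {
      vs <- which(lr == l)
      adj <- matrix(FALSE, length(vs), length(vs))
      for (ii in seq_along(vs)) for (jj in seq_along(vs)) {
        if (vs[jj] %in% idx[vs[ii], ] || vs[ii] %in% idx[vs[jj], ])
          adj[ii, jj] <- TRUE
      }
      visited <- rep(FALSE, length(vs))
      comp <- integer(length(vs))
      cid <- 0
      for (start in seq_along(vs)) {
        if (visited[start]) next
        cid <- cid + 1
        stack <- start
        while (length(stack)) {
          v <- stack[[1]]; stack <- stack[-1]
          if (visited[v]) next
          visited[v] <- TRUE; comp[v] <- cid
          stack <- c(stack, which(adj[v, ] & !visited))
        }
      }
      max(table(comp)) / length(vs)
    }, numeric(1)))
    expect_equal(graph_connectivity(Zr, lr, k_graph = k), oracle,
                 info = paste("seed", seed))
  }
})

test_that("embedding clustering recovers blobs and is seeded", {
  f <- blob_fixture()
  cl <- cluster_embeddings(f$Z, "gmm", param = 2, seed = 1)
  expect_equal(adjusted_rand_index(cl, f$labels), 1.0)
  expect_identical(cluster_embeddings(f$Z, "leiden", 0.5, seed = 3),
                   cluster_embeddings(f$Z, "leiden", 0.5, seed = 3))
  # very low resolution on one blob collapses to a single cluster
  one <- matrix(rnorm(200), 100, 2)
  expect_equal(length(unique(cluster_embeddings(one, "leiden", 1e-4,
                                                seed = 1))), 1L)
  # resolution search hits a requested cluster count
  cl5 <- cluster_embeddings(f$Z, "leiden", n_clusters = 2, seed = 1)
  expect_equal(length(unique(cl5)), 2L)
  expect_error(cluster_embeddings(f$Z, "gmm", param = 1000), "components")
})

test_that("metric report collects scores in [0, 1] and tidies", {
  f <- blob_fixture(n_per = 40)
  rep <- metric_report(f$Z, labels = f$labels, batches = f$batches,
                       k_region = 10, perplexity = 10, k_graph = 6)
  vals <- unlist(rep[setdiff(names(rep), "params")])
  expect_true(all(vals >= 0 & vals <= 1))
  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(nrow(td), 6)
})
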