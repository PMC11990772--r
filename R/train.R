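# Adam optimizer over a named list of parameter arrays.
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p))
                           else numeric(length(p))
  keys <- c("W1", "b1", "a", "W2", "b2")
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params[keys], zero_like),
       v = lapply(params[keys], zero_like))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  corr1 <- 1 - opt$beta1^opt$t
  corr2 <- 1 - opt$beta2^opt$t
  for (k in names(opt$m)) {
    g <- grads[[k]]
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * g
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * g^2
    step <- opt$lr * (opt$m[[k]] / corr1) /
      (sqrt(opt$v[[k]] / corr2) + opt$eps)
    params[[k]] <- params[[k]] - step
  }
  list(opt = opt, params = params)
}

zero_grads <- function(params) {
  list(W1 = matrix(0, nrow(params$W1), ncol(params$W1)),
       b1 = numeric(length(params$b1)), a = 0,
       W2 = matrix(0, nrow(params$W2), ncol(params$W2)),
       b2 = numeric(length(params$b2)))
}

add_grads <- function(acc, g, weight = 1) {
  for (k in names(acc)) acc[[k]] <- acc[[k]] + weight * g[[k]]
  acc
}

within_grad_sampled <- function(Z, coords, n_pairs) {
  n <- nrow(Z)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  ok <- i != j
  i <- i[ok]; j <- j[ok]
  dsn <- minmax_norm(sqrt(rowSums((coords[i, , drop = FALSE] -
                                     coords[j, , drop = FALSE])^2)))
  diff <- Z[i, , drop = FALSE] - Z[j, , drop = FALSE]
  dzv <- sqrt(rowSums(diff^2))
  rng <- range(dzv)
  den <- rng[2] - rng[1]
  dZ <- matrix(0, n, ncol(Z))
  if (den <= 0) return(list(loss = mean(dsn), dZ = dZ))
  dzn <- (dzv - rng[1]) / den
  loss <- mean(dsn * (1 - dzn))
  coef <- -dsn / (length(dzv) * den * pmax(dzv, 1e-12))
  G <- diff * coef
  agg <- rowsum(rbind(G, -G), group = c(i, j))
  dZ[as.integer(rownames(agg)), ] <- agg
  list(loss = loss, dZ = dZ)
}

#' Integrate multiple spatial transcriptomics slices
#'
#' Trains a single two-layer graph-convolutional encoder, shared across
#' slices, in two stages. Stage 1 pretrains with a plain InfoNCE loss over
#' uniformly perturbed graph views plus the spatial similarity constraint.
#' At the stage boundary, communities are detected per slice (Leiden on the
#' spatial graph, embedding- or expression-weighted) and their strengths
#' computed. Stage 2 switches to community-guided augmentation
#' (attribute voting and edge dropping) and the community-enhanced InfoNCE
#' loss with a scheduled bonus, and adds the cross-slice alignment term: MNN
#' pairs are re-detected on the current embeddings every `mnn_refresh`
#' epochs and drive a triplet hinge loss. The total objective is
#' \deqn{L = \sum_t L_t + \alpha \sum_t L^t_{within}
#'       + \beta \sum_{t_1 < t_2} L^{t_1 t_2}_{across},}
#' optimized with Adam (learning rate 0.001 by default), one update per
#' epoch with gradients accumulated over slices processed one at a time.
#'
#' @param slices list of >= 2 [st_slice] objects in state `log_normalized`
#'   with identical `gene_ids`.
#' @param epochs total training epochs (default 2000).
#' @param stage1_epochs epochs of random-view pretraining (default 200).
#' @param lr Adam learning rate.
#' @param h embedding dimension.
#' @param tau InfoNCE temperature.
#' @param alpha weight of the within-slice spatial constraint.
#' @param beta weight of the cross-slice triplet constraint.
#' @param theta triplet margin.
#' @param gamma_k0 warm-up epochs of the community bonus schedule
#'   (default `0.1 * epochs`).
#' @param gamma_max ceiling of the community bonus.
#' @param p_attr two attribute-masking hyperparameters (stage-2 views).
#' @param p_edge two edge-keep hyperparameters (stage-2 views).
#' @param p_attr_random,p_edge_random stage-1 uniform masking/dropping
#'   probabilities.
#' @param edge_keep_floor minimum stage-2 edge keep probability.
#' @param k_graph neighbor count for the spatial graph radius.
#' @param k_mnn MNN neighborhood size.
#' @param mnn_refresh epochs between MNN refreshes.
#' @param resolution Leiden resolution for community detection.
#' @param community_mode `"embedding"` (detect on the stage-1 embedding) or
#'   `"expression"`.
#' @param pair_subsample above this many spots the spatial constraint uses
#'   a random-pair subsample of 50,000 pairs per epoch.
#' @param scale_features z-score the gene columns of each slice before they
#'   enter the encoder (default `TRUE`). Log-normalized expression is
#'   nonnegative, which leaves the randomly initialized graph encoder
#'   nearly collapsed in cosine space; centering restores a usable
#'   contrastive signal. Community/augmentation weights still use the
#'   log-normalized values.
#' @param seed integer seed controlling every random draw.
#' @param verbose print progress every 100 epochs.
#' @return An `st_integration` object: `embeddings` (named list of n x h
#'   matrices), `slice_ids`, `history` (per-epoch loss components),
#'   `mnn_pairs` (last detected pairs per slice pair), `graphs`,
#'   `communities`, `params`, `config`.
#' @export
integrate_slices <- function(slices, epochs = 2000, stage1_epochs = 200,
                             lr = 1e-3, h = 50, tau = 0.02, alpha = 0.1,
                             beta = 1.0, theta = 1.0, gamma_k0 = NULL,
                             gamma_max = 1.0, p_attr = c(0.3, 0.4),
                             p_edge = c(0.9, 0.9), p_attr_random = 0.2,
                             p_edge_random = 0.2, edge_keep_floor = 0,
                             k_graph = 6, k_mnn = 5, mnn_refresh = 100,
                             resolution = 1.0,
                             community_mode = c("embedding", "expression"),
                             pair_subsample = 3000, scale_features = TRUE,
                             seed = 0, verbose = FALSE) {
  community_mode <- match.arg(community_mode)
  stopifnot(length(slices) >= 2, stage1_epochs < epochs)
  for (s in slices) {
    validate_slice(s)
    if (s$state != "log_normalized")
      stop("slice '", s$slice_id, "' must be log_normalized; run preprocess()")
  }
  gid <- slices[[1]]$gene_ids
  for (s in slices[-1]) {
    if (!identical(s$gene_ids, gid))
      stop("shape error: slices do not share an identical gene set/order; ",
           "run select_shared_hvgs()")
  }
  if (is.null(gamma_k0)) gamma_k0 <- round(0.1 * epochs)
  set.seed(seed)

  ns <- length(slices)
  sl_ids <- vapply(slices, `[[`, "", "slice_id")
  Xenc <- lapply(slices, function(s) {
    if (!scale_features) return(s$X)
    Xs <- scale(s$X)
    Xs[!is.finite(Xs)] <- 0  # constant genes
    attributes(Xs)[c("scaled:center", "scaled:scale")] <- NULL
    Xs
  })
  graphs <- lapply(slices, function(s) build_spatial_graph(s$coords, k_graph))
  Ahat_full <- lapply(graphs, normalize_adjacency)
  big <- vapply(slices, function(s) nrow(s$X) > pair_subsample, logical(1))
  Dsn <- vector("list", ns)
  for (t in seq_len(ns)) {
    if (!big[t]) Dsn[[t]] <- normalized_spatial_dist(slices[[t]]$coords)
  }

  params <- init_encoder(length(gid), h = h)
  opt <- adam_init(params, lr = lr)

  partitions <- vector("list", ns)
  attr_w <- vector("list", ns)
  edge_w <- vector("list", ns)
  slice_pairs <- if (ns >= 2) utils::combn(ns, 2, simplify = FALSE) else list()
  triplets <- vector("list", length(slice_pairs))
  mnn_pairs <- vector("list", length(slice_pairs))
  names(triplets) <- names(mnn_pairs) <-
    vapply(slice_pairs, function(p) paste(sl_ids[p], collapse = "|"), "")

  hist_rows <- vector("list", epochs)

  for (epoch in seq_len(epochs)) {
    stage2 <- epoch > stage1_epochs
    gamma_k <- if (stage2) gamma_schedule(epoch, gamma_k0, gamma_max) else 0

    # full-graph forward for every slice (alignment + spatial constraint)
    full_cache <- lapply(seq_len(ns), function(t)
      encoder_forward(Xenc[[t]], Ahat_full[[t]], params))
    Zfull <- lapply(full_cache, `[[`, "Z")

    # stage boundary: detect communities and freeze augmentation weights
    if (epoch == stage1_epochs + 1) {
      for (t in seq_len(ns)) {
        partitions[[t]] <- detect_communities(
          slices[[t]], graphs[[t]], mode = community_mode,
          embedding = Zfull[[t]], resolution = resolution,
          seed = seed + t)
        attr_w[[t]] <- attribute_mask_weights(slices[[t]]$X, partitions[[t]])
        edge_w[[t]] <- edge_mask_weights(graphs[[t]], partitions[[t]])
      }
    }

    # refresh MNN pairs / triplets on current embeddings
    if (stage2 && (epoch - stage1_epochs - 1) %% mnn_refresh == 0) {
      for (p in seq_along(slice_pairs)) {
        t1 <- slice_pairs[[p]][1]; t2 <- slice_pairs[[p]][2]
        prs <- find_mnn_pairs(Zfull[[t1]], Zfull[[t2]], k_mnn)
        mnn_pairs[[p]] <- prs
        if (nrow(prs) == 0) {
          warning("no MNN pairs between '", sl_ids[t1], "' and '",
                  sl_ids[t2], "' at epoch ", epoch, call. = FALSE)
          triplets[[p]] <- NULL
        } else {
          triplets[[p]] <- sample_triplets(prs, nrow(Zfull[[t1]]))
        }
      }
    }

    grads <- zero_grads(params)
    contrast_l <- within_l <- 0
    dZfull <- lapply(Zfull, function(Z) matrix(0, nrow(Z), ncol(Z)))

    for (t in seq_len(ns)) {
      g <- graphs[[t]]; X <- Xenc[[t]]
      if (stage2) {
        v1 <- sample_view(X, g, partitions[[t]], p_attr[1], p_edge[1],
                          edge_keep_floor, attr_w[[t]], edge_w[[t]])
        v2 <- sample_view(X, g, partitions[[t]], p_attr[2], p_edge[2],
                          edge_keep_floor, attr_w[[t]], edge_w[[t]])
      } else {
        v1 <- random_view(X, g, p_attr_random, p_edge_random)
        v2 <- random_view(X, g, p_attr_random, p_edge_random)
      }
      c1 <- encoder_forward(v1$X_masked,
                            normalized_operator_edges(v1$edges_kept,
                                                      g$n_spots), params)
      c2 <- encoder_forward(v2$X_masked,
                            normalized_operator_edges(v2$edges_kept,
                                                      g$n_spots), params)
      ig <- infonce_grad(c1$Z, c2$Z, tau,
                         partition = if (stage2) partitions[[t]] else NULL,
                         gamma = gamma_k)
      contrast_l <- contrast_l + ig$loss
      grads <- add_grads(grads, encoder_backward(ig$dZ1, c1, params))
      grads <- add_grads(grads, encoder_backward(ig$dZ2, c2, params))

      if (alpha != 0) {
        wg <- if (big[t])
          within_grad_sampled(Zfull[[t]], slices[[t]]$coords, 50000)
        else cpp_within(Zfull[[t]], Dsn[[t]], TRUE, single = TRUE)
        within_l <- within_l + wg$loss
        dZfull[[t]] <- dZfull[[t]] + alpha * wg$dZ
      }
    }

    across_l <- 0
    if (stage2 && beta != 0) {
      # The contrastive and spatial terms are scale-invariant, so the
      # embedding norm is unconstrained and a fixed margin would be
      # meaningless; the margin is therefore applied at the scale of the
      # embeddings' centered RMS spread (treated as a constant per step).
      allZ <- do.call(rbind, Zfull)
      ctr <- colMeans(allZ)
      sfac <- sqrt(max(mean(rowSums(sweep(allZ, 2, ctr)^2)), 1e-12))
      for (p in seq_along(slice_pairs)) {
        if (is.null(triplets[[p]])) next
        t1 <- slice_pairs[[p]][1]; t2 <- slice_pairs[[p]][2]
        tg <- triplet_grad(Zfull[[t1]] / sfac, Zfull[[t2]] / sfac,
                           triplets[[p]], theta)
        across_l <- across_l + tg$loss
        dZfull[[t1]] <- dZfull[[t1]] + (beta / sfac) * tg$dZa
        dZfull[[t2]] <- dZfull[[t2]] + (beta / sfac) * tg$dZp
      }
    }

    for (t in seq_len(ns)) {
      if (any(dZfull[[t]] != 0))
        grads <- add_grads(grads, encoder_backward(dZfull[[t]],
                                                   full_cache[[t]], params))
    }

    total_l <- contrast_l + alpha * within_l + beta * across_l
    if (!is.finite(total_l)) {
      stop("divergence error at epoch ", epoch, ": contrastive = ",
           signif(contrast_l, 4), ", within = ", signif(within_l, 4),
           ", across = ", signif(across_l, 4))
    }
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, stage = if (stage2) 2L else 1L, gamma = gamma_k,
      contrastive = contrast_l, within = within_l, across = across_l,
      total = total_l)

    st <- adam_step(opt, params, grads)
    opt <- st$opt
    params <- st$params

    if (verbose && (epoch %% 100 == 0 || epoch == 1)) {
      message(sprintf("epoch %4d [stage %d] total %.4f (contrast %.4f, within %.4f, across %.4f)",
                      epoch, if (stage2) 2 else 1, total_l, contrast_l,
                      within_l, across_l))
    }
  }

  embeddings <- lapply(seq_len(ns), function(t)
    encoder_forward(Xenc[[t]], Ahat_full[[t]], params)$Z)
  names(embeddings) <- sl_ids
  for (p in seq_along(slice_pairs)) {
    t1 <- slice_pairs[[p]][1]; t2 <- slice_pairs[[p]][2]
    mnn_pairs[[p]] <- find_mnn_pairs(embeddings[[t1]], embeddings[[t2]], k_mnn)
  }

  structure(
    list(embeddings = embeddings, slice_ids = sl_ids,
         history = do.call(rbind, hist_rows), mnn_pairs = mnn_pairs,
         graphs = graphs, communities = partitions, params = params,
         config = list(epochs = epochs, stage1_epochs = stage1_epochs,
                       lr = lr, h = h, tau = tau, alpha = alpha, beta = beta,
                       theta = theta, gamma_k0 = gamma_k0,
                       gamma_max = gamma_max, p_attr = p_attr,
                       p_edge = p_edge, p_attr_random = p_attr_random,
                       p_edge_random = p_edge_random,
                       edge_keep_floor = edge_keep_floor, k_graph = k_graph,
                       k_mnn = k_mnn, mnn_refresh = mnn_refresh,
                       resolution = resolution,
                       community_mode = community_mode, seed = seed)),
    class = "st_integration"
  )
}

#' @export
print.st_integration <- function(x, ...) {
  n <- vapply(x$embeddings, nrow, integer(1))
  cat("<st_integration> ", length(n), " slices (",
      paste(paste0(x$slice_ids, ": ", n), collapse = ", "), "), h = ",
      ncol(x$embeddings[[1]]), ", ", max(x$history$epoch), " epochs\n",
      sep = "")
  cat("final losses: total ", signif(utils::tail(x$history$total, 1), 5),
      "\n", sep = "")
  invisible(x)
}

#' Stack per-slice embeddings into one matrix
#'
#' @param integration an `st_integration`.
#' @return list with `Z` (row-bound embeddings) and `batch` (slice id per
#'   row).
#' @export
joint_embedding <- function(integration) {
  Z <- do.call(rbind, integration$embeddings)
  batch <- rep(integration$slice_ids,
               vapply(integration$embeddings, nrow, integer(1)))
  list(Z = Z, batch = batch)
}
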