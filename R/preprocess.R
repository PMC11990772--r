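#' Normalize and log-transform a slice
#'
#' Library-size normalization followed by a natural-log transform: each
#' spot's counts are scaled so they sum to `scale_total` (default 10,000),
#' then `log(1 + x)` is applied. Zero-count spots are kept as all-zero rows
#' (dropping them would desynchronize the coordinate table) and reported
#' with a warning.
#'
#' @param slice an [st_slice] in state `"raw"`.
#' @param scale_total target per-spot total after scaling.
#' @return The slice with transformed `X` and state `"log_normalized"`.
#' @export
preprocess <- function(slice, scale_total = 10000) {
  validate_slice(slice)
  if (slice$state == "log_normalized")
    stop("slice '", slice$slice_id, "' is already log_normalized; ",
         "refusing to double-transform")
  stopifnot(scale_total > 0)
  totals <- rowSums(slice$X)
  zero <- totals <= 0
  if (any(zero)) {
    warning(sum(zero), " spot(s) with zero total count kept as all-zero rows",
            call. = FALSE)
    totals[zero] <- 1  # leaves the all-zero rows untouched
  }
  slice$X <- log1p(slice$X * (scale_total / totals))
  slice$state <- "log_normalized"
  slice
}

# seurat_v3-style variance-stabilized variance per gene, computed on raw
# counts: fit a loess trend of log10(variance) on log10(mean), standardize
# counts by the trend sd with clipping at sqrt(n), and return the variance
# of the standardized values. Higher = more variable.
hvg_vst_score <- function(X, span = 0.3) {
  n <- nrow(X)
  mu <- colMeans(X)
  v <- apply(X, 2, stats::var)
  score <- rep(0, ncol(X))
  use <- v > 0 & mu > 0
  if (sum(use) < 4) {
    score[use] <- v[use]
    return(score)
  }
  fit <- stats::loess(log10(v[use]) ~ log10(mu[use]), span = span,
                      degree = 2)
  reg_sd <- sqrt(10^fit$fitted)
  clip <- sqrt(n)
  Xu <- X[, use, drop = FALSE]
  Zc <- sweep(sweep(Xu, 2, mu[use], "-"), 2, reg_sd, "/")
  Zc[Zc > clip] <- clip
  Zc[Zc < -clip] <- -clip
  score[use] <- colSums(Zc^2) / (n - 1) - colMeans(Zc)^2 * n / (n - 1)
  score
}

#' Select highly variable genes shared across slices
#'
#' Per slice, ranks genes by a variance-stabilized variance score computed
#' on raw counts (seurat_v3 flavor) and takes the top `n_top`; a slice with
#' fewer than `n_top` genes contributes its full gene list. Slices are then
#' subset to the intersection of the per-slice sets, with columns ordered
#' lexicographically by gene id so the output is deterministic.
#'
#' @param slices list of [st_slice] objects (>= 2) sharing a gene universe at
#'   least partially; states may be raw or log_normalized, but HVG scoring
#'   needs the raw counts, so pass `raw_slices` when the inputs are already
#'   transformed.
#' @param n_top number of variable genes per slice (default 3000).
#' @param raw_slices optional list of the same slices in state raw, used for
#'   scoring when `slices` are already normalized.
#' @return list with `slices` (subset, common gene order) and `genes`
#'   (the shared gene ids).
#' @export
select_shared_hvgs <- function(slices, n_top = 3000, raw_slices = NULL) {
  stopifnot(length(slices) >= 2, n_top >= 1)
  score_src <- if (is.null(raw_slices)) slices else raw_slices
  hvg_sets <- lapply(score_src, function(s) {
    if (ncol(s$X) < n_top) return(s$gene_ids)
    sc <- hvg_vst_score(s$X)
    s$gene_ids[order(sc, decreasing = TRUE)[seq_len(n_top)]]
  })
  shared <- Reduce(intersect, hvg_sets)
  if (length(shared) == 0) {
    stop("empty-gene-set error: no shared highly variable genes across ",
         "slices ", paste(vapply(slices, `[[`, "", "slice_id"),
                          collapse = ", "))
  }
  shared <- sort(shared)
  out <- lapply(slices, function(s) {
    idx <- match(shared, s$gene_ids)
    if (anyNA(idx))
      stop("empty-gene-set error: slice '", s$slice_id,
           "' is missing shared genes")
    s$X <- s$X[, idx, drop = FALSE]
    s$gene_ids <- shared
    validate_slice(s)
    s
  })
  list(slices = out, genes = shared)
}
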