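#' Simulation configuration for layered-tissue slices
#'
#' Describes a multi-slice simulated tissue: spots on jittered per-slice
#' lattices over a (possibly different) extent, spatially contiguous
#' horizontal-band domains shared across slices in relative coordinates
#' (emulating cortical-layer geometry), domain-specific marker programs,
#' and per-slice gene-wise multiplicative batch effects. Differing lattice
#' spacings emulate platforms of differing resolution.
#'
#' @param n_domains number of layered domains (>= 2).
#' @param extents list of per-slice `c(width, height)` extents.
#' @param spacings per-slice lattice spacing (one per slice).
#' @param n_genes total gene count.
#' @param n_markers_per_domain marker genes per domain.
#' @param marker_effect log-fold elevation of a marker inside its domain.
#' @param batch_shift_scale sd of the per-slice gene-wise log-normal batch
#'   factor (0 = no batch effect).
#' @param noise_model `"nb"` (negative binomial counts) or `"gaussian"`.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth_factors per-slice library-depth multiplier.
#' @param jitter lattice jitter as a fraction of the spacing.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline gene
#'   means.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_domains = 5,
                       extents = list(c(50, 30), c(100, 60)),
                       spacings = c(1, 2),
                       n_genes = 300,
                       n_markers_per_domain = 15,
                       marker_effect = 1.0,
                       batch_shift_scale = 1.0,
                       noise_model = c("nb", "gaussian"),
                       nb_dispersion = 0.5,
                       depth_factors = NULL,
                       jitter = 0.15,
                       base_meanlog = log(3), base_sdlog = 0.5,
                       seed = 0) {
  noise_model <- match.arg(noise_model)
  n_slices <- length(spacings)
  if (length(extents) != n_slices)
    stop("validation error: extents and spacings disagree on slice count")
  if (is.null(depth_factors)) depth_factors <- rep(1, n_slices)
  if (n_domains < 2) stop("validation error: n_domains must be >= 2")
  if (n_genes < n_domains * n_markers_per_domain)
    stop("validation error: need n_genes >= n_domains * n_markers_per_domain")
  structure(
    list(n_domains = n_domains, extents = extents, spacings = spacings,
         n_genes = n_genes, n_markers_per_domain = n_markers_per_domain,
         marker_effect = marker_effect,
         batch_shift_scale = batch_shift_scale, noise_model = noise_model,
         nb_dispersion = nb_dispersion, depth_factors = depth_factors,
         jitter = jitter, base_meanlog = base_meanlog,
         base_sdlog = base_sdlog, seed = seed),
    class = "sim_config"
  )
}

#' Simulate multi-slice layered-tissue data
#'
#' Generates raw-count slices with known ground truth. Domains are
#' horizontal bands in relative coordinates, so every slice shares the same
#' tissue layout regardless of its resolution. Per-domain expression
#' programs elevate that domain's markers by `marker_effect` on the log
#' scale; each slice applies its own gene-wise multiplicative log-normal
#' batch factor and depth multiplier before counts are drawn from the
#' configured noise model. Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return An `st_simulation`: `slices` (list of raw [st_slice] with domain
#'   labels), `labels` (per-slice factors), `true_means` (per-slice
#'   noiseless biological mean matrices, before batch/depth effects),
#'   `markers` (per-domain marker gene ids), `config`.
#' @export
simulate_slices <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_genes
  D <- config$n_domains
  gene_ids <- sprintf("gene_%03d", seq_len(m))
  base_mu <- stats::rlnorm(m, config$base_meanlog, config$base_sdlog)
  marker_idx <- matrix(sample.int(m, D * config$n_markers_per_domain),
                       nrow = D)
  markers <- lapply(seq_len(D), function(d) gene_ids[marker_idx[d, ]])
  names(markers) <- paste0("domain_", seq_len(D))

  # domain-by-gene biological mean matrix
  dom_mu <- matrix(rep(base_mu, each = D), D, m)
  for (d in seq_len(D)) {
    dom_mu[d, marker_idx[d, ]] <- dom_mu[d, marker_idx[d, ]] *
      exp(config$marker_effect)
  }

  n_slices <- length(config$spacings)
  slices <- labels <- true_means <- vector("list", n_slices)
  for (t in seq_len(n_slices)) {
    sp <- config$spacings[t]
    ext <- config$extents[[t]]
    nx <- max(2, round(ext[1] / sp))
    ny <- max(2, round(ext[2] / sp))
    gx <- rep(seq_len(nx), times = ny) * sp
    gy <- rep(seq_len(ny), each = nx) * sp
    n <- nx * ny
    coords <- cbind(
      x = gx + stats::runif(n, -config$jitter, config$jitter) * sp,
      y = gy + stats::runif(n, -config$jitter, config$jitter) * sp)
    yrel <- (gy - min(gy)) / (max(gy) - min(gy) + 1e-12)
    domain <- pmin(D, floor(yrel * D) + 1L)
    mu_bio <- dom_mu[domain, , drop = FALSE]

    batch_factor <- exp(stats::rnorm(m, 0, config$batch_shift_scale))
    mu_obs <- sweep(mu_bio, 2, batch_factor, "*") * config$depth_factors[t]

    X <- if (config$noise_model == "nb") {
      matrix(stats::rnbinom(n * m, mu = mu_obs,
                            size = 1 / config$nb_dispersion), n, m)
    } else {
      pmax(matrix(stats::rnorm(n * m, mu_obs, sqrt(mu_obs + 1e-8)), n, m), 0)
    }
    lab <- factor(paste0("domain_", domain),
                  levels = paste0("domain_", seq_len(D)))
    slices[[t]] <- st_slice(X, coords,
                            spot_ids = sprintf("s%d_%05d", t, seq_len(n)),
                            gene_ids = gene_ids,
                            slice_id = paste0("slice_", t),
                            labels = lab)
    labels[[t]] <- lab
    true_means[[t]] <- mu_bio
  }
  structure(
    list(slices = slices, labels = labels, true_means = true_means,
         markers = markers, config = config),
    class = "st_simulation"
  )
}

#' @export
print.st_simulation <- function(x, ...) {
  cat("<st_simulation> ", length(x$slices), " slices (",
      paste(vapply(x$slices, function(s) nrow(s$X), integer(1)),
            collapse = ", "), " spots), ",
      x$config$n_domains, " domains, ", x$config$n_genes, " genes\n",
      sep = "")
  invisible(x)
}
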