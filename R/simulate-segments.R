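#' Simulate a spatial segment count matrix with a confounded ligand-receptor pair
#'
#' Generates a genes x segments count matrix emulating a segment-based
#' spatial profiling run: by default 60 segments (30 per tissue, three
#' sorted compartments, slides of 24/24/12 interleaved across tissues so
#' slide is not nested in tissue). Three generative layers are planted:
#'
#' * Background genes follow a log-normal-Poisson model whose log-scale
#'   variance is partitioned into a tissue-by-compartment ("biological")
#'   share, a slide ("batch") share and residual noise, at the configured
#'   proportions (defaults 0.60 / 0.12).
#' * The ligand-receptor pair is driven by a shared latent niche factor plus
#'   a latent immune-content factor, through a Gaussian copula onto
#'   negative-binomial marginals, so the configured marginal rank
#'   correlation is achieved (up to tie and normalization attenuation).
#' * The immune marker genes load on the same immune-content factor, making
#'   the composite immune score an effective adjustment covariate for the
#'   partial-correlation analysis.
#'
#' All genes share a per-segment depth factor; co-expression analyses are
#' intended to run on Q3-normalized values, which removes it.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `segments` (a [segment_matrix()]) and
#'   `truth` (planted latent correlation, loadings and variance shares).
#' @export
simulate_segments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (abs(config$lr_pair$rho) >= 1)
    stop("|latent correlation| must be < 1")
  with_seed(config$seed, simulate_segments_impl(config))
}

simulate_segments_impl <- function(config) {
  des <- config$segment_design
  lr <- config$lr_pair
  genes <- sim_gene_ids(config)

  n_seg <- des$n_per_tissue * length(des$tissues)
  # interleave tissues, then assign compartments in balanced blocks and
  # slides sequentially: every slide then contains both tissues
  meta <- data.frame(
    tissue = rep(des$tissues, length.out = n_seg),
    compartment = rep(des$compartments, length.out = n_seg))
  meta$slide <- rep(names(des$slide_sizes), times = des$slide_sizes)
  meta$segment_id <- sprintf("seg_%02d", seq_len(n_seg))
  rownames(meta) <- meta$segment_id

  depth <- rlnorm(n_seg, 0, des$depth_sd)

  niche <- rnorm(n_seg)    # latent niche factor driving the LR pair
  immune <- rnorm(n_seg)   # latent immune-content confounder

  a <- lr$direct; b <- lr$confounder_loading
  res_sd <- sqrt(max(1 - a^2 - b^2, 0))
  z_l <- a * niche + b * immune + res_sd * rnorm(n_seg)
  z_r <- a * niche + b * immune + res_sd * rnorm(n_seg)

  counts <- matrix(0, nrow = length(genes), ncol = n_seg,
                   dimnames = list(genes, meta$segment_id))

  copula_counts <- function(z, mu) {
    # monotone map of the Gaussian latent onto NB marginals; depth enters
    # through mu and is removed again by Q3 normalization downstream
    qnbinom(pnorm(z), mu = mu * depth, size = 1 / des$dispersion)
  }
  counts[lr$ligand, ] <- copula_counts(z_l, lr$mu_ligand)
  counts[lr$receptor, ] <- copula_counts(z_r, lr$mu_receptor)

  il <- des$immune_loading
  mu_marker <- exp(runif(length(config$immune_markers), log(80), log(300)))
  for (i in seq_along(config$immune_markers)) {
    z_m <- il * immune + sqrt(1 - il^2) * rnorm(n_seg)
    counts[config$immune_markers[i], ] <- copula_counts(z_m, mu_marker[i])
  }

  # background genes: planted variance partition on the log scale
  special <- c(lr$ligand, lr$receptor, config$immune_markers)
  bg <- setdiff(genes, special)
  base_log <- runif(length(bg), log(des$base_mean_range[1]),
                    log(des$base_mean_range[2]))
  # biological structure is additive in tissue and compartment (half the
  # planted biological variance each), batch structure follows slide
  tis_f <- factor(meta$tissue)
  comp_f <- factor(meta$compartment)
  slide_f <- factor(meta$slide)
  s_bio <- sqrt(des$bio_var_share / 2) * des$sigma_log
  s_batch <- sqrt(des$batch_var_share) * des$sigma_log
  s_res <- sqrt(1 - des$bio_var_share - des$batch_var_share) * des$sigma_log
  # each pattern row is standardized across segments so the planted
  # variance shares are exact regardless of level counts and imbalance
  std_rows <- function(m) {
    m <- m - rowMeans(m)
    sds <- sqrt(rowMeans(m^2))
    m / ifelse(sds > 0, sds, 1)
  }
  draw_pattern <- function(f) {
    b <- matrix(rnorm(length(bg) * nlevels(f)), ncol = nlevels(f))
    std_rows(b[, as.integer(f), drop = FALSE])
  }
  log_mu <- base_log +
    s_bio * draw_pattern(tis_f) +
    s_bio * draw_pattern(comp_f) +
    s_batch * draw_pattern(slide_f) +
    s_res * std_rows(matrix(rnorm(length(bg) * n_seg), ncol = n_seg))
  # smooth-muscle program genes additionally elevated in stromal segments
  sm <- intersect(c("MYH11", "ACTA2", "DES", "TAGLN"), bg)
  if (length(sm)) {
    stroma <- meta$compartment == "Stroma"
    log_mu[match(sm, bg), stroma] <- log_mu[match(sm, bg), stroma] + 1
  }
  mu_bg <- exp(log_mu) * rep(depth, each = length(bg))
  counts[bg, ] <- rpois(length(mu_bg), mu_bg)

  meta <- meta[, c("segment_id", "tissue", "compartment", "slide")]
  list(segments = segment_matrix(counts, meta),
       truth = list(lr = list(ligand = lr$ligand, receptor = lr$receptor,
                              rho = lr$rho, direct = a,
                              confounder_loading = b),
                    bio_var_share = des$bio_var_share,
                    batch_var_share = des$batch_var_share))
}
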