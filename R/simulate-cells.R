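# Run expr with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a single-cell count matrix with planted structure
#'
#' Draws a genes x cells count matrix following the statistical structure the
#' downstream analyses assume: negative-binomial background counts with
#' gene-specific means and a shared dispersion, per-cell depth variation,
#' group-targeted multiplicative expression programs, and sparsely expressed
#' genes whose cells are expressors with a group-specific probability and,
#' when expressing, carry log-normally distributed intensities. Per-cell QC
#' metrics (detected genes, UMIs, mitochondrial fraction) describe the
#' whole-transcriptome scale and include a configurable fraction of planted
#' low-quality cells; they are simulated alongside the (down-sampled) gene
#' panel rather than recomputed from it.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `cells` (a [cell_matrix()]) and `truth`, a
#'   ground-truth table holding, per sparse gene and group, the expressing
#'   fraction and intensity; per program gene, the planted log2 effect; and
#'   the configured composition and ligand-receptor latent correlation.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cells_impl(config))
}

simulate_cells_impl <- function(config) {
  groups <- names(config$n_patients_per_group)
  genes <- sim_gene_ids(config)
  sparse_genes <- vapply(config$sparse_gene_specs, `[[`, "", "gene")

  # cell metadata skeleton, grouped by group then patient
  meta <- do.call(rbind, lapply(groups, function(g) {
    np <- config$n_patients_per_group[[g]]
    data.frame(group = g,
               patient = rep(sprintf("%s_P%d", g, seq_len(np)),
                             each = config$cells_per_patient))
  }))
  n_cells <- nrow(meta)
  meta$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  meta$group <- factor(meta$group, levels = groups)

  # cell types drawn from the group composition simplex
  types <- colnames(config$celltype_proportions)
  meta$cell_type <- unlist(lapply(groups, function(g) {
    n_g <- sum(meta$group == g)
    sample(types, n_g, replace = TRUE,
           prob = config$celltype_proportions[g, ])
  }))

  # gene-specific background means (log-uniform); sparse genes have no
  # background component, they are generated by the expressor mechanism only
  lam <- exp(runif(length(genes), log(config$base_mean_range[1]),
                   log(config$base_mean_range[2])))
  names(lam) <- genes
  lam[sparse_genes] <- 0

  depth <- rlnorm(n_cells, 0, config$depth_sd)

  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, meta$cell_id))
  for (g in groups) {
    lam_g <- lam
    pg <- config$program_specs[config$program_specs$group == g, , drop = FALSE]
    if (nrow(pg)) lam_g[pg$gene] <- lam_g[pg$gene] * 2^pg$log2fc
    for (p in unique(meta$patient[meta$group == g])) {
      idx <- which(meta$group == g & meta$patient == p)
      # patient-level biological heterogeneity on background means
      lam_p <- lam_g * rlnorm(length(lam_g), 0, config$patient_effect_sd)
      mu <- outer(lam_p, depth[idx])
      counts[, idx] <- rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion)
    }
  }

  # sparse genes: Bernoulli expressor per cell at the group fraction;
  # expressors draw a log-normal intensity (geometric mean = configured
  # intensity), scaled by cell depth and rounded to a positive count
  for (sp in config$sparse_gene_specs) {
    for (g in groups) {
      idx <- which(meta$group == g)
      expressor <- idx[rbinom(length(idx), 1L, sp$fraction[[g]]) == 1L]
      if (length(expressor)) {
        val <- rlnorm(length(expressor), log(sp$intensity[[g]]), sp$sigma)
        counts[sp$gene, expressor] <- pmax(1L, as.integer(round(val * depth[expressor])))
      }
    }
  }

  # whole-transcriptome QC metrics with planted low-quality cells
  n_det <- as.integer(round(rlnorm(n_cells, log(2500), 0.25)))
  umi_ratio <- rlnorm(n_cells, log(3), 0.2)
  n_umi <- pmax(n_det, as.integer(round(n_det * umi_ratio)))
  mito <- rbeta(n_cells, 2, 18)
  n_bad <- round(config$low_quality_fraction * n_cells)
  if (n_bad > 0) {
    bad <- sample.int(n_cells, n_bad)
    defect <- sample(c("genes", "umi", "mito"), n_bad, replace = TRUE)
    lowg <- bad[defect == "genes"]
    n_det[lowg] <- sample(50:499, length(lowg), replace = TRUE)
    n_umi[lowg] <- pmax(n_det[lowg],
                        as.integer(round(n_det[lowg] * runif(length(lowg), 1.2, 3))))
    lowu <- bad[defect == "umi"]
    n_det[lowu] <- sample(500:900, length(lowu), replace = TRUE)
    n_umi[lowu] <- vapply(n_det[lowu],
                          function(k) sample(seq(k, 999L), 1L), integer(1))
    highm <- bad[defect == "mito"]
    mito[highm] <- runif(length(highm), 0.26, 0.9)
  }
  meta$n_genes_detected <- n_det
  meta$n_umi <- n_umi
  meta$mito_fraction <- mito
  meta <- meta[, c("cell_id", "group", "patient", "cell_type",
                   "n_genes_detected", "n_umi", "mito_fraction")]
  rownames(meta) <- meta$cell_id

  truth_sparse <- do.call(rbind, lapply(config$sparse_gene_specs, function(sp) {
    data.frame(gene = sp$gene, group = groups,
               fraction = as.numeric(sp$fraction[groups]),
               intensity = as.numeric(sp$intensity[groups]))
  }))

  list(cells = cell_matrix(counts, meta),
       truth = list(sparse = truth_sparse,
                    programs = config$program_specs,
                    celltype_proportions = config$celltype_proportions,
                    lr = config$lr_pair[c("ligand", "receptor", "rho",
                                          "confounder_loading")]))
}
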