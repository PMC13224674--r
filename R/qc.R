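#' Cell quality-control thresholds
#'
#' Default thresholds follow standard single-cell practice: cells with fewer
#' than 500 detected genes, fewer than 1000 UMIs, or more than 25%
#' mitochondrial content are removed. Removal is strict (`<` / `>`), so a
#' cell sitting exactly on a threshold is kept.
#'
#' @param min_genes Minimum detected genes (kept if `>=`).
#' @param min_umi Minimum UMI count (kept if `>=`).
#' @param max_mito Maximum mitochondrial fraction (kept if `<=`), in (0, 1].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500L, min_umi = 1000L, max_mito = 0.25) {
  if (min_genes <= 0 || min_umi <= 0 || max_mito <= 0 || max_mito > 1)
    stop("thresholds must be positive, with max_mito in (0, 1]")
  structure(list(min_genes = min_genes, min_umi = min_umi,
                 max_mito = max_mito), class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells satisfying all three criteria: detected genes >= `min_genes`,
#' UMIs >= `min_umi` and mitochondrial fraction <= `max_mito`. The report
#' counts how many cells each criterion flags (a cell can be flagged by
#' several) and the joint removal.
#'
#' @param m A [cell_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `cells` (the column-subset [cell_matrix()]) and
#'   `report`: named counts `n_input`, `n_kept`, `removed_genes`,
#'   `removed_umi`, `removed_mito`, `removed_total`.
#' @export
qc_filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  meta <- m$cell_meta
  needed <- c("n_genes_detected", "n_umi", "mito_fraction")
  if (!all(needed %in% names(meta)) || anyNA(meta[needed]))
    stop("cell metadata must contain complete QC fields: ",
         paste(needed, collapse = ", "))
  fail_genes <- meta$n_genes_detected < thresholds$min_genes
  fail_umi <- meta$n_umi < thresholds$min_umi
  fail_mito <- meta$mito_fraction > thresholds$max_mito
  keep <- !(fail_genes | fail_umi | fail_mito)
  out <- cell_matrix(m$counts[, keep, drop = FALSE],
                     meta[keep, , drop = FALSE])
  list(cells = out,
       report = c(n_input = nrow(meta),
                  n_kept = sum(keep),
                  removed_genes = sum(fail_genes),
                  removed_umi = sum(fail_umi),
                  removed_mito = sum(fail_mito),
                  removed_total = sum(!keep)))
}

#' Log-normalize a count matrix
#'
#' Computes `log(1 + scale * count / column_total)` per entry, the standard
#' counts-per-`scale` log transform. Columns with zero total are returned as
#' all-zero with a warning.
#'
#' @param m A [cell_matrix()], [segment_matrix()] or plain matrix
#'   (genes x units) of non-negative counts.
#' @param scale Positive library-size target (default 1e4).
#' @return A sparse (or dense, matching the input) matrix of normalized
#'   values with the same dimnames.
#' @export
lognormalize <- function(m, scale = 1e4) {
  counts <- if (inherits(m, "cell_matrix") || inherits(m, "segment_matrix"))
    m$counts else m
  if (scale <= 0) stop("scale must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " column(s) with zero total; returned as all-zero")
    totals[zero] <- 1
  }
  if (is(counts, "sparseMatrix")) {
    norm <- counts
    norm@x <- log1p(scale * norm@x / rep.int(totals, diff(norm@p)))
    norm
  } else {
    log1p(sweep(counts, 2, totals / scale, "/"))
  }
}
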