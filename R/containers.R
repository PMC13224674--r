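#' Single-cell count matrix with per-cell metadata
#'
#' Bundles a genes x cells integer count matrix with the per-cell metadata
#' required by the downstream analyses: tissue group, patient of origin,
#' cell-type annotation and the three quality-control metrics (detected
#' genes, total UMIs, mitochondrial fraction).
#'
#' @param counts Non-negative integer matrix (base or \pkg{Matrix} sparse),
#'   genes in rows (unique rownames required), cells in columns.
#' @param cell_meta `data.frame` with one row per cell and columns
#'   `group`, `patient`, `cell_type`, `n_genes_detected`, `n_umi`,
#'   `mito_fraction`. `group` may be a factor; its levels declare the label
#'   set (otherwise the observed labels do).
#'
#' @return An object of class `cell_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `cell_meta`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene identifiers)")
  if (!is.data.frame(cell_meta))
    stop("cell_meta must be a data.frame")
  needed <- c("group", "patient", "cell_type",
              "n_genes_detected", "n_umi", "mito_fraction")
  missing <- setdiff(needed, names(cell_meta))
  if (length(missing))
    stop("cell_meta lacks required columns: ", paste(missing, collapse = ", "))
  if (nrow(cell_meta) != ncol(counts))
    stop("cell_meta rows (", nrow(cell_meta), ") must match counts columns (",
         ncol(counts), ")")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.factor(cell_meta$group)) cell_meta$group <- factor(cell_meta$group)
  bad <- with(cell_meta, n_umi < n_genes_detected | n_genes_detected < 0)
  if (any(bad))
    stop("cell_meta violates n_umi >= n_genes_detected >= 0 for ",
         sum(bad), " cell(s)")
  if (any(cell_meta$mito_fraction < 0 | cell_meta$mito_fraction > 1))
    stop("mito_fraction must lie in [0, 1]")
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts), " cells\n",
      sep = "")
  tab <- table(x$cell_meta$group)
  cat("groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Spatial segment count matrix with segment metadata
#'
#' Holds a genes x segments count matrix from a segment-based spatial
#' platform together with per-segment annotation (tissue, sorted cellular
#' compartment, slide) and, once computed, a normalized expression matrix.
#' The per-segment detection rate (fraction of panel genes with count > 0)
#' is computed at construction.
#'
#' @param counts Non-negative numeric matrix, genes x segments, with unique
#'   rownames.
#' @param segment_meta `data.frame` with columns `tissue`, `compartment`,
#'   `slide`, one row per segment.
#' @param normalized Optional numeric matrix of the same shape as `counts`.
#'
#' @return An object of class `segment_matrix` with elements `counts`,
#'   `segment_meta`, `normalized` (possibly `NULL`) and `detection_rate`.
#' @export
segment_matrix <- function(counts, segment_meta, normalized = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("counts must have unique rownames (gene identifiers)")
  needed <- c("tissue", "compartment", "slide")
  missing <- setdiff(needed, names(segment_meta))
  if (length(missing))
    stop("segment_meta lacks required columns: ",
         paste(missing, collapse = ", "))
  if (nrow(segment_meta) != ncol(counts))
    stop("segment_meta rows must match counts columns")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!identical(dim(normalized), dim(counts)))
      stop("normalized must have the same dimensions as counts")
  }
  structure(list(counts = counts,
                 segment_meta = segment_meta,
                 normalized = normalized,
                 detection_rate = colMeans(counts > 0)),
            class = "segment_matrix")
}

#' @export
print.segment_matrix <- function(x, ...) {
  cat("segment_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " segments", if (!is.null(x$normalized)) " (normalized)", "\n", sep = "")
  print(table(x$segment_meta$tissue, x$segment_meta$compartment))
  invisible(x)
}
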