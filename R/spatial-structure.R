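#' Co-expression modules by complete-linkage hierarchical clustering
#'
#' Standardizes each gene's expression profile across units, clusters genes
#' by complete linkage on Euclidean distances and cuts the tree into `k`
#' modules. Genes are processed in lexicographic order and modules are
#' renumbered by first appearance in that order, so the assignment is
#' invariant to the input gene order up to nothing (labels included).
#'
#' @param expr Numeric matrix (genes x units), typically normalized.
#' @param genes Genes to cluster (default: all rows); must number >= `k`.
#' @param k Number of modules.
#' @return Named integer vector of module assignments, with the `hclust`
#'   tree in attribute `"tree"`.
#' @export
coexpression_modules <- function(expr, genes = rownames(expr), k = 3) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("genes not found: ",
                            paste(missing, collapse = ", "))
  genes <- sort(unique(genes))
  if (k > length(genes)) stop("k exceeds the number of genes")
  prof <- as.matrix(expr[genes, , drop = FALSE])
  sds <- apply(prof, 1, sd)
  prof <- (prof - rowMeans(prof)) / ifelse(sds > 0, sds, 1)
  tree <- hclust(dist(prof), method = "complete")
  raw <- cutree(tree, k = k)
  relabel <- match(raw, unique(raw))  # renumber by first appearance
  out <- setNames(relabel, genes)
  attr(out, "tree") <- tree
  out
}

#' Partition segment expression variance into biological and batch fractions
#'
#' Quantifies how much transcriptional variance is attributable to biology
#' (tissue and compartment) versus technical batch (slide): genes are
#' centered and scaled across segments, a PCA is taken over segments, and
#' for each component with variance share `f_i` the R-squared of a linear
#' model of the component scores on `tissue + compartment` (and separately
#' on `slide`) is computed. The reported fraction is `sum(f_i * R2_i)`.
#' The two regressions are run separately, matching how the two fractions
#' are reported; they need not be additive. If slide is nested within
#' tissue the batch fraction is confounded and a warning is attached.
#'
#' @param expr Numeric matrix (genes x segments) of normalized (typically
#'   log-scale) expression.
#' @param meta `data.frame` with `tissue`, `compartment`, `slide` per
#'   segment; each factor needs >= 2 levels.
#' @return A list with `biological`, `batch` and `residual` fractions (in
#'   `[0, 1]`; residual is `1 - biological - batch`, floored at 0).
#' @export
variance_partition <- function(expr, meta) {
  expr <- as.matrix(expr)
  if (ncol(expr) != nrow(meta)) stop("meta rows must match segments")
  tissue <- factor(meta$tissue)
  comp <- factor(meta$compartment)
  slide <- factor(meta$slide)
  if (nlevels(tissue) < 2 || nlevels(comp) < 2 || nlevels(slide) < 2)
    stop("tissue, compartment and slide each need >= 2 levels")
  if (all(rowSums(table(slide, tissue) > 0) == 1))
    warning("slide is nested within tissue; batch fraction is confounded")
  sds <- apply(expr, 1, sd)
  expr <- expr[sds > 0, , drop = FALSE]
  xs <- (expr - rowMeans(expr)) / sds[sds > 0]
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  f <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- which(f > 1e-12)
  bio <- sum(vapply(keep, function(i)
    f[i] * summary(lm(pc$x[, i] ~ tissue + comp))$r.squared, numeric(1)))
  batch <- sum(vapply(keep, function(i)
    f[i] * summary(lm(pc$x[, i] ~ slide))$r.squared, numeric(1)))
  list(biological = bio, batch = batch,
       residual = max(1 - bio - batch, 0))
}
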