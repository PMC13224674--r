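#' Construct a gene set
#'
#' @param name Set name.
#' @param genes Character vector of unique gene identifiers (non-empty).
#' @return A list of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) stop("gene set must be non-empty")
  if (anyDuplicated(genes)) stop("gene set members must be unique")
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (name, description, genes).
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(setNames(names(sets), names(sets)),
         function(nm) gene_set(nm, unique(sets[[nm]])))
}

#' Built-in signature gene sets
#'
#' The printed signatures used throughout the analysis: smooth muscle
#' (MYH11, ACTA2, DES, TAGLN), cytotoxicity (GZMB, PRF1, GNLY), exhaustion
#' (CTLA4, PDCD1, LAG3, HAVCR2, TIGIT), immune checkpoints and the
#' segment-level immune markers (CD68, CD3D, CD3E, PTPRC, CD4, CD8A). The
#' broader pathway sets (immune response, angiogenesis, hormone response,
#' ECM) are small non-authoritative defaults built from the genes the
#' analysis names; supply curated GMT sets for real use.
#'
#' @return Named list of [gene_set()] objects.
#' @export
default_signatures <- function() {
  defs <- list(
    smooth_muscle = c("MYH11", "ACTA2", "DES", "TAGLN"),
    cytotoxicity = c("GZMB", "PRF1", "GNLY"),
    exhaustion = c("CTLA4", "PDCD1", "LAG3", "HAVCR2", "TIGIT"),
    immune_checkpoint = c("CTLA4", "PDCD1", "CD274"),
    immune_markers = c("CD68", "CD3D", "CD3E", "PTPRC", "CD4", "CD8A"),
    immune_response = c("CCL19", "CCL21", "CCR7", "PTPRC", "CD3D"),
    angiogenesis = c("VEGFA", "PDGFRB", "ANGPT2"),
    hormone_response = c("ESR1", "PGR", "ESR2"),
    ecm_organization = c("COL1A1", "COL3A1", "FN1"))
  lapply(setNames(names(defs), names(defs)),
         function(nm) gene_set(nm, defs[[nm]]))
}

#' Gene-set activity score
#'
#' The unweighted mean of (log-)normalized expression of the set's genes in
#' each unit (cell or segment). Set genes absent from the matrix are dropped
#' with a warning; no background-gene correction is applied.
#'
#' @param expr Expression matrix (genes x units), typically log-normalized.
#' @param set A [gene_set()] or character vector of genes.
#' @return Named numeric vector of per-unit scores.
#' @export
geneset_score <- function(expr, set) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0)
    stop("no gene of the set is present in the matrix")
  if (length(present) < length(genes))
    warning("dropping ", length(genes) - length(present),
            " set gene(s) absent from the matrix")
  scores <- Matrix::colSums(expr[present, , drop = FALSE]) / length(present)
  setNames(as.numeric(scores), colnames(expr))
}

#' Per-group summary of a score vector
#'
#' @param s Numeric score per unit.
#' @param groups Group label per unit (same length as `s`).
#' @return `data.frame` with per-group `n`, `mean`, `sd`, `median`, `q1`,
#'   `q3`. Empty groups are omitted with a warning.
#' @export
group_score_summary <- function(s, groups) {
  if (length(s) != length(groups))
    stop("scores and group labels must align")
  if (!is.factor(groups)) groups <- factor(groups)
  empty <- setdiff(levels(groups), unique(as.character(groups)))
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(s, groups, drop = TRUE), function(v) {
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_,
               median = qs[2], q1 = qs[1], q3 = qs[3])
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' ROC area under the curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half: the
#' probability that a random positive scores above a random negative.
#' Invariant under strictly monotone transformations of the values.
#'
#' @param values Numeric scores.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is taken as positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stop("values and labels must align")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both label classes must be present")
  r <- rank(values)  # average ranks handle ties as 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
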