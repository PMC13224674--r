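#' Filter spatial segments by gene detection rate
#'
#' Keeps segments whose detection rate (fraction of panel genes with
#' count > 0) strictly exceeds `min_detection`.
#'
#' @param s A [segment_matrix()].
#' @param min_detection Detection-rate threshold (default 0.30).
#' @return The column-subset [segment_matrix()].
#' @export
qc_filter_segments <- function(s, min_detection = 0.30) {
  stopifnot(inherits(s, "segment_matrix"))
  keep <- s$detection_rate > min_detection
  segment_matrix(s$counts[, keep, drop = FALSE],
                 s$segment_meta[keep, , drop = FALSE],
                 normalized = if (!is.null(s$normalized))
                   s$normalized[, keep, drop = FALSE])
}

#' Q3 (upper-quartile) segment normalization
#'
#' Scales each segment by the ratio of a common target to the segment's
#' 75th percentile of positive counts, the convention of segment-based
#' spatial platforms. The target is the geometric mean of all segment Q3s,
#' so after normalization every segment has an identical Q3 (within 1e-9)
#' and re-running the normalization changes nothing. Segments whose Q3 over
#' positive counts is zero are excluded with a warning.
#'
#' @param s A [segment_matrix()].
#' @return The [segment_matrix()] with the `normalized` matrix filled and
#'   per-segment factors stored in attribute `"q3_factors"` of that matrix.
#' @export
q3_normalize <- function(s) {
  stopifnot(inherits(s, "segment_matrix"))
  q3 <- apply(s$counts, 2, function(cnt) {
    pos <- cnt[cnt > 0]
    if (length(pos) == 0) 0 else unname(quantile(pos, 0.75))
  })
  bad <- q3 <= 0
  counts <- s$counts; meta <- s$segment_meta
  if (any(bad)) {
    warning("excluding ", sum(bad), " segment(s) with zero Q3")
    counts <- counts[, !bad, drop = FALSE]
    meta <- meta[!bad, , drop = FALSE]
    q3 <- q3[!bad]
  }
  target <- exp(mean(log(q3)))
  factors <- target / q3
  norm <- sweep(counts, 2, factors, "*")
  attr(norm, "q3_factors") <- factors
  segment_matrix(counts, meta, normalized = norm)
}

#' Harmonize genes across single-cell and spatial platforms
#'
#' Returns the genes consistently detected on both platforms: symbols with
#' more than `min_count` counts in more than `min_frac` of units (strict
#' inequalities) in both the cell and the segment data.
#'
#' @param cells A [cell_matrix()].
#' @param segs A [segment_matrix()].
#' @param min_count Count threshold (strict).
#' @param min_frac Fraction-of-units threshold (strict).
#' @return Character vector of shared passing gene symbols.
#' @export
harmonize_genes <- function(cells, segs, min_count = 5, min_frac = 0.10) {
  stopifnot(inherits(cells, "cell_matrix"), inherits(segs, "segment_matrix"))
  pass <- function(counts) {
    frac <- Matrix::rowSums(counts > min_count) / ncol(counts)
    rownames(counts)[frac > min_frac]
  }
  shared <- intersect(pass(cells$counts), pass(segs$counts))
  if (length(shared) == 0)
    stop("no gene passes the detection criterion on both platforms")
  shared
}
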