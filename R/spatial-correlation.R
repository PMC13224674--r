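#' All-pairs Spearman correlation records
#'
#' Spearman correlation (average-rank ties) for every gene pair across
#' units, with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` and BH adjustment within the tested
#' family. Constant genes yield flagged records with `rho = NA`.
#'
#' @param expr Numeric matrix (genes x units), typically normalized segment
#'   expression; needs >= 3 units.
#' @param genes Optional subset of genes to test (default: all rows).
#' @return `data.frame` with columns `gene_a`, `gene_b`, `rho`, `p`, `q`,
#'   `n`, `constant`.
#' @export
spearman_matrix <- function(expr, genes = NULL) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) stop("genes not found: ",
                              paste(missing, collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  expr <- as.matrix(expr)
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 units")
  constant <- apply(expr, 1, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(cor(t(expr), method = "spearman"))
  pair <- which(upper.tri(rho), arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(expr)[pair[, 1]],
                    gene_b = rownames(expr)[pair[, 2]],
                    rho = rho[pair], n = n)
  out$constant <- constant[pair[, 1]] | constant[pair[, 2]]
  out$rho[out$constant] <- NA_real_
  tstat <- out$rho * sqrt((n - 2) / pmax(1 - out$rho^2, 1e-300))
  out$p <- 2 * pt(-abs(tstat), df = n - 2)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out[, c("gene_a", "gene_b", "rho", "p", "q", "n", "constant")]
}

#' Screen ligand-receptor pairs for spatial co-expression
#'
#' Looks up each candidate pair in a table of correlation records and flags
#' it as spatially co-expressed when `rho > rho_threshold` and the
#' BH-adjusted p-value is below `q_threshold`. Pairs with members absent
#' from the records are skipped with a warning.
#'
#' @param records Output of [spearman_matrix()].
#' @param pairs List of 2-vectors `c(ligand, receptor)` (or a 2-column
#'   matrix / data.frame).
#' @param rho_threshold,q_threshold Screen thresholds (defaults 0.7 and
#'   0.001).
#' @return `data.frame` with one row per found pair: `ligand`, `receptor`,
#'   `rho`, `p`, `q`, `n`, `passes_screen`.
#' @export
ligand_receptor_screen <- function(records, pairs, rho_threshold = 0.7,
                                   q_threshold = 0.001) {
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) unlist(pairs[i, 1:2]))
  if (!is.list(pairs)) pairs <- list(pairs)
  key <- paste(records$gene_a, records$gene_b)
  key_rev <- paste(records$gene_b, records$gene_a)
  rows <- lapply(pairs, function(pr) {
    hit <- match(paste(pr[1], pr[2]), key)
    if (is.na(hit)) hit <- match(paste(pr[1], pr[2]), key_rev)
    if (is.na(hit)) {
      warning("pair not found in records: ", pr[1], "-", pr[2])
      return(NULL)
    }
    rec <- records[hit, ]
    data.frame(ligand = pr[1], receptor = pr[2], rho = rec$rho,
               p = rec$p, q = rec$q, n = rec$n,
               passes_screen = !is.na(rec$rho) && !is.na(rec$q) &&
                 rec$rho > rho_threshold && rec$q < q_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composite immune score per spatial segment
#'
#' Mean normalized expression of the immune marker genes (macrophage CD68,
#' T-cell CD3D/CD3E, pan-immune PTPRC, T-subset CD4/CD8A) in each segment;
#' the adjustment covariate for the partial-correlation analysis.
#'
#' @param expr Normalized segment expression matrix (genes x segments).
#' @param markers Marker genes (at least one must be present).
#' @return Named numeric score per segment.
#' @export
immune_score_segments <- function(expr, markers = c("CD68", "CD3D", "CD3E",
                                                    "PTPRC", "CD4", "CD8A")) {
  geneset_score(expr, gene_set("immune_markers", markers))
}

#' First-order partial Spearman correlation
#'
#' Rank-transforms all three vectors, then removes the covariate through
#' the first-order formula
#' `rho_xy.z = (rho_xy - rho_xz * rho_yz) / sqrt((1-rho_xz^2)(1-rho_yz^2))`,
#' with a two-sided p-value from the t distribution on `n - 3` degrees of
#' freedom. Used to check that a ligand-receptor association survives
#' adjustment for segment immune content.
#'
#' @param x,y,z Numeric vectors of equal length `n >= 4`; all non-constant.
#' @return A list with `partial_rho`, `p`, and `n`.
#' @export
partial_spearman <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1 ||
      length(unique(z)) == 1) stop("x, y, z must be non-constant")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("covariate perfectly correlated with x or y; partial undefined")
  pr <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  pr <- max(min(pr, 1), -1)
  tstat <- pr * sqrt((n - 3) / max(1 - pr^2, 1e-300))
  list(partial_rho = pr, p = 2 * pt(-abs(tstat), df = n - 3), n = n)
}
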