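#' Geometric mean of positive values
#'
#' `exp(mean(log(x)))`. Expressor values are positive by construction
#' (positivity is count > 0), so zeros are excluded upstream.
#'
#' @param values Positive numeric vector, length >= 1.
#' @return The geometric mean.
#' @export
geometric_mean_positive <- function(values) {
  if (length(values) == 0) stop("geometric mean undefined for empty input")
  if (any(values <= 0)) stop("values must be positive")
  exp(mean(log(values)))
}

#' Welch's t-test on log-transformed values
#'
#' Applies Welch's unequal-variance t-test to the natural logs of two
#' positive samples, with Welch-Satterthwaite degrees of freedom. The base
#' of the logarithm cancels in the statistic. Two identical zero-variance
#' samples give t = 0, p = 1.
#'
#' @param x,y Positive numeric vectors, each of length >= 2.
#' @return A list with `t`, `df` and two-sided `p`.
#' @export
welch_t_log <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 values")
  if (any(x <= 0) || any(y <= 0)) stop("values must be positive")
  lx <- log(x); ly <- log(y)
  v1 <- var(lx) / length(lx); v2 <- var(ly) / length(ly)
  if (v1 + v2 == 0) {
    if (mean(lx) == mean(ly)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance with unequal means: t undefined")
  }
  t <- (mean(lx) - mean(ly)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 /
    (v1^2 / (length(lx) - 1) + v2^2 / (length(ly) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-step differential test for sparsely expressed genes
#'
#' For genes expressed in a small fraction of cells, comparing all cells
#' between groups dilutes real differences with non-expressing cells. This
#' test separates the two phenomena: step (i) compares the expressing-cell
#' fractions (expression > 0) with a pooled two-proportion z-test; step (ii)
#' compares, among expressors only, the geometric mean of expression levels
#' with Welch's t-test on log values. The two p-values are reported
#' separately and never combined. If either group has fewer than 2
#' expressors, step (ii) is marked not evaluable while step (i) is still
#' returned.
#'
#' @param expr Expression matrix (genes x cells); raw or monotone-normalized
#'   counts (positivity is invariant; the intensity ratio is reported on the
#'   scale supplied).
#' @param groups Group label per column of `expr`.
#' @param gene Gene identifier.
#' @param group_a,group_b The two groups to compare (a vs b).
#' @return One-row `data.frame` with columns `gene`, `group_a`, `group_b`,
#'   `frac1`, `frac2`, `z`, `p_frac`, `n_expr1`, `n_expr2`, `geomean1`,
#'   `geomean2`, `intensity_ratio`, `t`, `df`, `p_intensity`,
#'   `intensity_evaluable`, plus `q_frac`/`q_intensity` slots (NA here;
#'   filled across genes by [sparse_gene_test_table()]).
#' @seealso [sparse_gene_test_table()] for multi-gene tables with BH
#'   adjustment.
#' @export
two_step_sparse_test <- function(expr, groups, gene, group_a, group_b) {
  if (!gene %in% rownames(expr)) stop("gene not found: ", gene)
  groups <- as.character(groups)
  ia <- groups == group_a; ib <- groups == group_b
  if (!any(ia) || !any(ib)) stop("both groups must be non-empty")
  va <- as.numeric(expr[gene, ia]); vb <- as.numeric(expr[gene, ib])
  ka <- sum(va > 0); kb <- sum(vb > 0)
  zt <- two_proportion_ztest(ka, length(va), kb, length(vb))
  ea <- va[va > 0]; eb <- vb[vb > 0]
  evaluable <- length(ea) >= 2 && length(eb) >= 2
  g1 <- if (length(ea)) geometric_mean_positive(ea) else NA_real_
  g2 <- if (length(eb)) geometric_mean_positive(eb) else NA_real_
  if (evaluable) {
    wt <- welch_t_log(ea, eb)
  } else {
    wt <- list(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  data.frame(gene = gene, group_a = group_a, group_b = group_b,
             frac1 = ka / length(va), frac2 = kb / length(vb),
             z = zt$z, p_frac = zt$p,
             n_expr1 = length(ea), n_expr2 = length(eb),
             geomean1 = g1, geomean2 = g2,
             intensity_ratio = g1 / g2,
             t = wt$t, df = wt$df, p_intensity = wt$p,
             intensity_evaluable = evaluable,
             q_frac = NA_real_, q_intensity = NA_real_)
}

#' Two-step sparse-gene tests over genes and comparisons
#'
#' Runs [two_step_sparse_test()] for every gene and group comparison and
#' applies Benjamini-Hochberg adjustment separately to the frequency-step
#' and intensity-step p-values, each within its comparison (the two steps
#' are distinct quantities and form separate families).
#'
#' @param expr Expression matrix (genes x cells).
#' @param groups Group label per column.
#' @param genes Character vector of genes to test.
#' @param comparisons List of 2-vectors `c(group_a, group_b)`.
#' @return `data.frame`, one row per gene x comparison, with `q_frac` and
#'   `q_intensity` filled.
#' @export
sparse_gene_test_table <- function(expr, groups, genes, comparisons) {
  if (!is.list(comparisons)) comparisons <- list(comparisons)
  res <- do.call(rbind, lapply(comparisons, function(cmp) {
    rows <- do.call(rbind, lapply(genes, function(g)
      two_step_sparse_test(expr, groups, g, cmp[1], cmp[2])))
    rows$q_frac <- bh_adjust(rows$p_frac)
    ok <- !is.na(rows$p_intensity)
    rows$q_intensity[ok] <- bh_adjust(rows$p_intensity[ok])
    rows
  }))
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, preserving input order.
#' Delegates to [stats::p.adjust()] after validating the input range.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted q-values, `q >= p`, in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
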