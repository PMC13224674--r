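#' Aggregate single cells to patient-level pseudo-bulk profiles
#'
#' Sums counts over each patient-tissue combination, yielding one integer
#' column per sample so that downstream inference treats patients, not
#' cells, as replicates. Samples are ordered by group, then patient.
#'
#' @param m A [cell_matrix()].
#' @return An object of class `pseudobulk`: a list with `counts`
#'   (genes x samples integer matrix), `sample_meta` (`sample`, `patient`,
#'   `group`) and `size_factors` (`NULL` until estimated).
#' @export
aggregate_pseudobulk <- function(m) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  if (anyNA(meta$patient) || anyNA(meta$group))
    stop("patient and group labels must be present")
  key <- interaction(meta$group, meta$patient, drop = TRUE, sep = "||")
  first <- !duplicated(key)
  sm <- data.frame(group = as.character(meta$group)[first],
                   patient = as.character(meta$patient)[first])
  ord <- order(sm$group, sm$patient)
  sm <- sm[ord, , drop = FALSE]
  sm$sample <- paste(sm$patient, sep = "")
  sm <- data.frame(sample = sm$patient, patient = sm$patient,
                   group = sm$group)
  # indicator matrix cells x samples; sparse crossproduct does the summing
  idx <- match(paste(meta$group, meta$patient, sep = "||"),
               paste(sm$group, sm$patient, sep = "||"))
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(meta)), j = idx,
                              x = 1, dims = c(nrow(meta), nrow(sm)))
  counts <- as.matrix(m$counts %*% ind)
  dimnames(counts) <- list(rownames(m$counts), sm$sample)
  rownames(sm) <- sm$sample
  structure(list(counts = counts, sample_meta = sm, size_factors = NULL),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("pseudobulk: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  print(table(x$sample_meta$group))
  invisible(x)
}

#' Remove weakly expressed genes from a pseudo-bulk matrix
#'
#' Keeps genes with at least `min_count` counts in at least `min_samples`
#' samples, the reading of the low-expression filter that preserves genes
#' with replicated signal. Both parameters are exposed; setting
#' `min_samples = 1` with `min_count` on row sums reproduces the alternative
#' "total-count" reading.
#'
#' @param pb A `pseudobulk` object.
#' @param min_count Minimum count per sample.
#' @param min_samples Minimum number of samples reaching `min_count`.
#' @return The filtered `pseudobulk`.
#' @export
filter_low_expression <- function(pb, min_count = 10, min_samples = 3) {
  stopifnot(inherits(pb, "pseudobulk"))
  keep <- rowSums(pb$counts >= min_count) >= min_samples
  pb$counts <- pb$counts[keep, , drop = FALSE]
  pb
}

#' Median-of-ratios size factors
#'
#' The normalization underlying count-model differential expression: a
#' per-gene geometric-mean reference is computed over genes positive in all
#' samples; each sample's factor is the median of its count-to-reference
#' ratios; factors are rescaled to geometric mean 1. If no gene is positive
#' in every sample, falls back to total-count ratios with a warning.
#'
#' @param pb A `pseudobulk` object or a plain genes x samples count matrix.
#' @return Named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no gene positive in all samples; using total-count ratios")
    sf <- colSums(counts)
  } else {
    logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- apply(counts[allpos, , drop = FALSE], 2,
                function(cnt) exp(median(log(cnt) - logref)))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

# Per-gene method-of-moments NB dispersion from normalized counts, pooled
# across the two groups. Var(y/s) = mu * mean(1/s) + alpha * mu^2 within a
# group with common mu; solve for alpha and pool by within-group df.
moment_dispersion <- function(q, s, grp_list) {
  num <- 0; den <- 0
  for (idx in grp_list) {
    if (length(idx) < 2) next
    m <- mean(q[idx])
    if (m <= 0) next
    a <- (var(q[idx]) - m * mean(1 / s[idx])) / m^2
    num <- num + (length(idx) - 1) * a
    den <- den + (length(idx) - 1)
  }
  if (den == 0) return(1e-8)
  max(num / den, 1e-8)
}

#' Negative-binomial Wald differential expression on pseudo-bulk counts
#'
#' A transparent per-gene NB generalized linear model with log link, offset
#' `log(size factor)` and a single group coefficient, fitted by iteratively
#' reweighted least squares with the gene's dispersion estimated by the
#' method of moments on normalized counts (floored at 1e-8). The Wald
#' statistic `coefficient / SE` is referred to a t distribution with
#' residual degrees of freedom (samples - 2); with per-gene plug-in
#' dispersions at few replicates this small-sample reference is required
#' for calibrated null p-values, which a standard-normal reference does not
#' deliver (see the methods vignette). P-values are BH-adjusted across
#' genes and `log2fc = coefficient / ln 2` (positive means higher in
#' `group_a`).
#'
#' @param pb A `pseudobulk` object (typically after
#'   [filter_low_expression()]).
#' @param group_a,group_b Groups to compare (a vs b); each needs >= 2
#'   samples.
#' @param lfc_threshold,alpha Significance thresholds: a gene is called
#'   significant when `|log2fc| > lfc_threshold` and `q < alpha`.
#' @param max_iter Maximum IRLS iterations; non-converged genes are flagged
#'   and their p-values set to NA.
#' @return `data.frame` of class `de_result`, one row per gene: `gene`,
#'   `mean_a`, `mean_b` (normalized means), `log2fc`, `se` (of log2fc),
#'   `stat`, `df`, `p`, `q`, `significant`, `converged`. Thresholds are
#'   stored as attributes.
#' @export
nb_wald_de <- function(pb, group_a, group_b, lfc_threshold = 1, alpha = 0.05,
                       max_iter = 50L) {
  stopifnot(inherits(pb, "pseudobulk"))
  grp <- pb$sample_meta$group
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  sel <- c(ia, ib)
  counts <- pb$counts[, sel, drop = FALSE]
  sf <- pb$size_factors
  sf <- if (is.null(sf)) size_factors(counts) else sf[sel]
  x <- as.numeric(seq_along(sel) <= length(ia))  # 1 = group_a
  X <- cbind(1, x)
  off <- log(sf)
  n <- length(sel)
  out <- data.frame(gene = rownames(counts),
                    mean_a = NA_real_, mean_b = NA_real_,
                    log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                    df = n - 2, p = NA_real_, converged = FALSE)
  for (i in seq_len(nrow(counts))) {
    y <- counts[i, ]
    q <- y / sf
    ma <- mean(q[x == 1]); mb <- mean(q[x == 0])
    out$mean_a[i] <- ma; out$mean_b[i] <- mb
    if (ma == 0 || mb == 0) {
      # boundary MLE: fold change not identifiable on the log scale
      out$log2fc[i] <- log2((ma + 0.5) / (mb + 0.5))
      next
    }
    disp <- moment_dispersion(q, sf, list(which(x == 1), which(x == 0)))
    beta <- c(log(mb), log(ma) - log(mb))
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta) + off
      mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
      w <- mu / (1 + disp * mu)
      z <- (eta - off) + (y - mu) / mu
      XtW <- t(X * w)
      fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
      if (is.null(fit)) break
      delta <- drop(fit) - beta
      beta <- drop(fit)
      if (max(abs(delta)) < 1e-8) { conv <- TRUE; break }
    }
    if (!conv) { out$log2fc[i] <- beta[2] / log(2); next }
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    w <- mu / (1 + disp * mu)
    cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
    if (is.null(cov)) next
    se_ln <- sqrt(cov[2, 2])
    out$log2fc[i] <- beta[2] / log(2)
    out$se[i] <- se_ln / log(2)
    out$stat[i] <- beta[2] / se_ln
    out$p[i] <- 2 * pt(-abs(out$stat[i]), df = n - 2)
    out$converged[i] <- TRUE
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < alpha &
    abs(out$log2fc) > lfc_threshold
  rownames(out) <- NULL
  attr(out, "groups") <- c(group_a = group_a, group_b = group_b)
  attr(out, "lfc_threshold") <- lfc_threshold
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", "data.frame")
  out
}

#' Significant genes from a DE result
#'
#' Applies the thresholds stored in the result: `|log2fc| >` the fold-change
#' threshold and `q <` the FDR level.
#'
#' @param d A `de_result` from [nb_wald_de()].
#' @return Character vector of significant gene identifiers.
#' @export
significant_genes <- function(d) {
  stopifnot(inherits(d, "de_result"))
  d$gene[d$significant]
}
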