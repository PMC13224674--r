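#' Per-group cell-type composition
#'
#' Tabulates cell-type fractions within each tissue group, together with an
#' aggregate immune fraction (T cells + macrophages + B cells + NK cells,
#' for whichever of those labels are present).
#'
#' @param m A [cell_matrix()].
#' @param immune_types Cell-type labels counted into the immune aggregate.
#' @return A `data.frame` with one row per group x cell type (`group`,
#'   `cell_type`, `n`, `fraction`; fractions sum to 1 within each group) and
#'   an attribute `"immune"`: a `data.frame` of per-group immune fractions.
#'   Groups with no cells are omitted with a warning.
#' @export
composition_table <- function(m, immune_types = c("T cells", "Macrophages",
                                                  "B cells", "NK cells")) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  if (anyNA(meta$cell_type)) stop("cell_type labels must be present")
  empty <- setdiff(levels(meta$group), unique(as.character(meta$group)))
  if (length(empty))
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
  tab <- table(group = factor(meta$group), cell_type = meta$cell_type)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  frac <- tab / rowSums(tab)
  out <- as.data.frame(tab, responseName = "n")
  out$fraction <- as.data.frame(frac)$Freq
  imm <- data.frame(
    group = rownames(frac),
    immune_fraction = rowSums(frac[, colnames(frac) %in% immune_types,
                                   drop = FALSE]))
  attr(out, "immune") <- imm
  out
}

#' Positive-cell proportions per group
#'
#' A cell is positive for a gene when its raw count exceeds zero (equivalent
#' under any monotone normalization). Returns one record per group.
#'
#' @param m A [cell_matrix()].
#' @param gene Gene identifier.
#' @return `data.frame` with columns `group`, `k_positive`, `n_total`,
#'   `fraction`.
#' @export
positive_cell_proportions <- function(m, gene) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!gene %in% rownames(m$counts))
    stop("gene not found: ", gene)
  pos <- as.numeric(m$counts[gene, ]) > 0
  grp <- factor(m$cell_meta$group)
  k <- tapply(pos, grp, sum)
  n <- tapply(pos, grp, length)
  keep <- !is.na(n)
  data.frame(group = names(k)[keep],
             k_positive = as.integer(k[keep]),
             n_total = as.integer(n[keep]),
             fraction = as.numeric(k[keep] / n[keep]),
             row.names = NULL)
}

#' Two-proportion z-test (pooled variance)
#'
#' Classic pooled two-proportion z statistic with a two-sided normal
#' p-value; no continuity correction, so `z^2` equals the Pearson chi-square
#' statistic of the 2x2 table. When both proportions are 0 or both are 1
#' the statistic is defined as 0 with p = 1.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return A list with elements `z` and `p`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2) {
  if (any(c(n1, n2) < 1) || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("require 0 <= k <= n and n >= 1 in both samples")
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Fold enrichment of two proportions
#'
#' @param p1,p2 Fractions; `p2` must be positive.
#' @return `p1 / p2`. Summary displays round to one decimal.
#' @export
fold_enrichment <- function(p1, p2) {
  if (p2 <= 0) stop("reference proportion must be positive; fold undefined")
  p1 / p2
}

#' Per-patient positive-cell frequencies
#'
#' Computes the positive-cell fraction for a gene within every
#' patient-group cell subset, then summarizes per group with the mean,
#' sample SD (n - 1) and range over patients. Patients contributing zero
#' cells are excluded with a warning.
#'
#' @param m A [cell_matrix()].
#' @param gene Gene identifier.
#' @return A list with `per_patient` (`group`, `patient`, `k_positive`,
#'   `n_total`, `fraction`) and `summary` (`group`, `n_patients`, `mean`,
#'   `sd`, `min`, `max`).
#' @export
per_patient_frequencies <- function(m, gene) {
  stopifnot(inherits(m, "cell_matrix"))
  if (!gene %in% rownames(m$counts)) stop("gene not found: ", gene)
  if (anyNA(m$cell_meta$patient)) stop("patient IDs must be present")
  pos <- as.numeric(m$counts[gene, ]) > 0
  meta <- m$cell_meta
  pp <- aggregate(pos, by = list(group = meta$group, patient = meta$patient),
                  FUN = function(x) c(k = sum(x), n = length(x)))
  per_patient <- data.frame(group = pp$group, patient = pp$patient,
                            k_positive = pp$x[, "k"], n_total = pp$x[, "n"])
  if (any(per_patient$n_total == 0)) {
    warning("excluding patient(s) with zero cells")
    per_patient <- per_patient[per_patient$n_total > 0, ]
  }
  per_patient$fraction <- per_patient$k_positive / per_patient$n_total
  per_patient <- per_patient[order(per_patient$group, per_patient$patient), ]
  rownames(per_patient) <- NULL
  summ <- do.call(rbind, lapply(split(per_patient, per_patient$group, drop = TRUE),
    function(d) data.frame(group = d$group[1], n_patients = nrow(d),
                           mean = mean(d$fraction),
                           sd = if (nrow(d) > 1) sd(d$fraction) else NA_real_,
                           min = min(d$fraction), max = max(d$fraction))))
  rownames(summ) <- NULL
  list(per_patient = per_patient, summary = summ)
}
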