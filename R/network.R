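#' Pathway-level signaling network
#'
#' Summarizes pathway activity into a node/edge table: one node per gene
#' set, sized by the mean absolute log2 fold change of its member genes in
#' a differential-expression result and labelled with the group whose mean
#' activity score is largest; edges connect pathway pairs whose activity
#' scores correlate (Spearman) above a threshold across units.
#'
#' @param set_scores Numeric matrix of pathway scores, sets x units (e.g.
#'   rows built with [geneset_score()]).
#' @param groups Group label per unit.
#' @param de A `de_result` from [nb_wald_de()].
#' @param sets Named list of [gene_set()] objects matching the rows of
#'   `set_scores`.
#' @param edge_threshold Score-correlation threshold for an edge.
#' @return A list of class `pathway_network` with `nodes` (`pathway`,
#'   `size`, `specificity`) and `edges` (`from`, `to`, `weight`).
#' @export
pathway_network <- function(set_scores, groups, de, sets,
                            edge_threshold = 0.5) {
  set_scores <- as.matrix(set_scores)
  if (is.null(rownames(set_scores)))
    rownames(set_scores) <- names(sets)
  if (!all(rownames(set_scores) %in% names(sets)))
    stop("set_scores rows must match the names of sets")
  if (length(groups) != ncol(set_scores))
    stop("groups must align with set_scores columns")
  nodes <- do.call(rbind, lapply(rownames(set_scores), function(nm) {
    members <- intersect(sets[[nm]]$genes, de$gene)
    size <- if (length(members) == 0) {
      warning("pathway ", nm, " has no gene in the DE result; size 0")
      0
    } else mean(abs(de$log2fc[match(members, de$gene)]), na.rm = TRUE)
    gm <- tapply(set_scores[nm, ], factor(groups), mean)
    data.frame(pathway = nm, size = size,
               specificity = names(gm)[which.max(gm)])
  }))
  nodes <- nodes[order(nodes$pathway), ]
  rownames(nodes) <- NULL
  rho <- suppressWarnings(cor(t(set_scores), method = "spearman"))
  pair <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = rownames(set_scores)[pair[, 1]],
                      to = rownames(set_scores)[pair[, 2]],
                      weight = rho[pair])
  edges <- edges[!is.na(edges$weight) & edges$weight > edge_threshold, ]
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("pathway_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (threshold ", x$edge_threshold, ")\n", sep = "")
  invisible(x)
}

#' Classify lesion groups as immune-hot or immune-cold niches
#'
#' An operational rule making the qualitative hot/cold dichotomy
#' reproducible: a group is called immune-hot when its immune cell fraction
#' is at least `hot_immune` and its checkpoint score exceeds the reference
#' group's mean; immune-cold when the immune fraction is at most
#' `cold_immune` and the checkpoint score does not exceed the reference
#' mean; otherwise indeterminate. The thresholds are explicit parameters of
#' this package, not quantities estimated from data. Missing inputs yield
#' an indeterminate call with the reason recorded.
#'
#' @param immune_fractions Named numeric vector of per-group immune cell
#'   fractions (e.g. the `"immune"` attribute of [composition_table()]).
#' @param checkpoint_scores Named numeric vector of per-group mean
#'   checkpoint/exhaustion scores.
#' @param reference Reference group name (must appear in
#'   `checkpoint_scores`).
#' @param sparse_results Optional table from [sparse_gene_test_table()]
#'   used to set a per-group chemokine flag: any tested gene with a higher
#'   expressing fraction than the reference comparison at `q_frac < 0.05`.
#' @param hot_immune,cold_immune Immune-fraction thresholds.
#' @return `data.frame` with one row per group: `group`, `immune_fraction`,
#'   `checkpoint_score`, `chemokine_flag`, `call`, `reason`.
#' @export
classify_niche <- function(immune_fractions, checkpoint_scores,
                           reference = "Ctrl", sparse_results = NULL,
                           hot_immune = 0.30, cold_immune = 0.20) {
  if (!reference %in% names(checkpoint_scores))
    stop("reference group absent from checkpoint_scores")
  ref_score <- checkpoint_scores[[reference]]
  groups <- union(names(immune_fractions), names(checkpoint_scores))
  out <- do.call(rbind, lapply(groups, function(g) {
    imm <- immune_fractions[g]
    chk <- checkpoint_scores[g]
    flag <- FALSE
    if (!is.null(sparse_results)) {
      sub <- sparse_results[sparse_results$group_a == g &
                              sparse_results$group_b == reference, ]
      flag <- nrow(sub) > 0 &&
        any(!is.na(sub$q_frac) & sub$q_frac < 0.05 & sub$frac1 > sub$frac2)
    }
    if (is.na(imm) || is.na(chk)) {
      call <- "indeterminate"
      reason <- "missing immune fraction or checkpoint score"
    } else if (imm >= hot_immune && chk > ref_score) {
      call <- "immune-hot"; reason <- ""
    } else if (imm <= cold_immune && chk <= ref_score) {
      call <- "immune-cold"; reason <- ""
    } else {
      call <- "indeterminate"
      reason <- "between thresholds"
    }
    data.frame(group = g, immune_fraction = unname(imm),
               checkpoint_score = unname(chk), chemokine_flag = flag,
               call = call, reason = reason)
  }))
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(hot_immune = hot_immune,
                               cold_immune = cold_immune)
  attr(out, "reference") <- reference
  out
}
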