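seg_meta <- function(n) {
  data.frame(segment_id = sprintf("s%02d", seq_len(n)),
             tissue = rep(c("EuE", "EcP"), length.out = n),
             compartment = rep(c("Macrophages", "Epithelium", "Stroma"),
                               length.out = n),
             slide = rep(c("S1", "S2"), each = ceiling(n / 2))[seq_len(n)])
}

test_that("segment QC removes low-detection segments strictly", {
  counts <- matrix(1, 100, 3, dimnames = list(sprintf("g%03d", 1:100), NULL))
  counts[30:100, 2] <- 0   # 29% detection
  counts[60:100, 3] <- 0   # 59% detection
  colnames(counts) <- c("hi", "low", "mid")
  s <- segment_matrix(counts, seg_meta(3))
  kept <- qc_filter_segments(s, min_detection = 0.30)
  expect_identical(colnames(kept$counts), c("hi", "mid"))
  # brute-force predicate on random data
  set.seed(61)
  rnd <- random_counts(50, 12, lambda = 0.4)
  s2 <- segment_matrix(rnd, seg_meta(12))
  kept2 <- qc_filter_segments(s2, min_detection = 0.25)
  brute <- colnames(rnd)[colMeans(rnd > 0) > 0.25]
  expect_identical(colnames(kept2$counts), brute)
  # all 60 default synthetic segments pass
  seg <- seg_fixture()$segments
  expect_equal(ncol(qc_filter_segments(seg)$counts), 60)
})

test_that("Q3 normalization equalizes segment upper quartiles", {
  set.seed(62)
  base <- random_counts(200, 1, lambda = 40)[, 1]
  counts <- cbind(a = base, b = 3 * base)
  rownames(counts) <- sprintf("g%03d", 1:200)
  s <- segment_matrix(counts, seg_meta(2))
  sn <- q3_normalize(s)
  # a segment at 3x another normalizes to identical values
  expect_equal(sn$normalized[, "a"], sn$normalized[, "b"], tolerance = 1e-9)
  # single segment: unchanged (its own Q3 is the target)
  s1 <- segment_matrix(counts[, 1, drop = FALSE], seg_meta(1))
  expect_equal(q3_normalize(s1)$normalized, counts[, 1, drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  # post-normalization positive-count Q3 identical across segments
  rnd <- random_counts(300, 8, lambda = 25)
  sr <- q3_normalize(segment_matrix(rnd, seg_meta(8)))
  q3s <- apply(sr$normalized, 2, function(v) quantile(v[v > 0], 0.75))
  expect_lt(max(q3s) - min(q3s), 1e-9)
  # idempotence: renormalizing the normalized matrix is a no-op
  sr2 <- q3_normalize(segment_matrix(sr$normalized, seg_meta(8)))
  expect_equal(sr2$normalized, sr$normalized, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("gene harmonization applies strict dual-platform detection", {
  cellcounts <- rbind(SHARED = c(6, 6, 6, 0), BOUNDARY = c(5, 5, 5, 5),
                      CELLONLY = c(9, 9, 9, 9), RARE = c(6, 0, 0, 0))
  colnames(cellcounts) <- paste0("c", 1:4)
  cm <- cell_matrix(cellcounts, data.frame(
    cell_id = colnames(cellcounts), group = "A", patient = "P",
    cell_type = "T cells", n_genes_detected = 4L, n_umi = 24L,
    mito_fraction = 0))
  segcounts <- rbind(SHARED = c(10, 10, 0), BOUNDARY = c(50, 50, 50),
                     SEGONLY = c(8, 8, 8), RARE = c(0, 0, 0))
  colnames(segcounts) <- paste0("s", 1:3)
  sm <- segment_matrix(segcounts, seg_meta(3))
  shared <- harmonize_genes(cm, sm, min_count = 5, min_frac = 0.10)
  # SHARED passes both; BOUNDARY fails cells (count exactly 5 is not > 5);
  # CELLONLY/SEGONLY fail the other platform; RARE fails both
  expect_identical(shared, "SHARED")
  # brute-force two-predicate intersection on random data
  set.seed(63)
  cc <- random_counts(40, 30, lambda = 3)
  sc <- random_counts(40, 10, lambda = 3)
  cm2 <- cell_matrix(cc, data.frame(
    cell_id = colnames(cc), group = "A", patient = "P", cell_type = "T cells",
    n_genes_detected = 1L, n_umi = 100L, mito_fraction = 0))
  sm2 <- segment_matrix(sc, seg_meta(10))
  got <- harmonize_genes(cm2, sm2, min_count = 2, min_frac = 0.2)
  brute <- intersect(
    rownames(cc)[rowMeans(cc > 2) > 0.2],
    rownames(sc)[rowMeans(sc > 2) > 0.2])
  expect_identical(got, brute)
})

test_that("Spearman records match a brute-force rank-Pearson oracle", {
  set.seed(64)
  expr <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("u", 1:10)))
  expr["g2", ] <- expr["g1", ]^3        # monotone transform of g1
  expr["g5", ] <- 2                      # constant gene
  rec <- spearman_matrix(expr)
  pick <- function(a, b) rec[rec$gene_a == a & rec$gene_b == b, ]
  # monotone transform preserves rank correlation exactly
  expect_equal(pick("g1", "g2")$rho, 1, tolerance = 1e-12)
  # constant gene flagged with NA correlation
  expect_true(all(rec$constant[rec$gene_a == "g5" | rec$gene_b == "g5"]))
  expect_true(all(is.na(rec$rho[rec$constant])))
  for (i in 1:3) for (j in (i + 1):4) {
    brute <- cor(rank(expr[i, ]), rank(expr[j, ]))
    expect_equal(pick(paste0("g", i), paste0("g", j))$rho, brute,
                 tolerance = 1e-12)
  }
  # p-values from the t approximation, BH within the family
  ok <- !is.na(rec$p)
  expect_equal(rec$q[ok], bh_adjust(rec$p[ok]))
  expect_error(spearman_matrix(expr[, 1:2]), "at least 3")
})

test_that("the ligand-receptor screen applies both thresholds", {
  rec <- data.frame(gene_a = c("L1", "L2"), gene_b = c("R1", "R2"),
                    rho = c(0.71, 0.9), p = c(0.001, 1e-10),
                    q = c(0.01, 1e-8), n = 60, constant = FALSE)
  out <- ligand_receptor_screen(rec, list(c("L1", "R1"), c("L2", "R2")))
  expect_false(out$passes_screen[1])  # rho passes but q = 0.01 > 0.001
  expect_true(out$passes_screen[2])
  expect_warning(ligand_receptor_screen(rec, list(c("L9", "R9"))),
                 "not found")
  # reversed gene order is found too
  out2 <- ligand_receptor_screen(rec, list(c("R2", "L2")))
  expect_true(out2$passes_screen)
})

test_that("partial Spearman matches the residualized-ranks oracle", {
  set.seed(65)
  for (i in 1:30) {
    x <- rnorm(30); y <- rnorm(30); z <- rnorm(30)
    got <- partial_spearman(x, y, z)
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    ex <- residuals(lm(rx ~ rz)); ey <- residuals(lm(ry ~ rz))
    expect_equal(got$partial_rho, cor(ex, ey), tolerance = 1e-10)
  }
  # y = x: partial correlation 1 whatever the covariate
  x <- rnorm(20)
  expect_equal(partial_spearman(x, x, rnorm(20))$partial_rho, 1,
               tolerance = 1e-12)
  # independent covariate leaves the association essentially unchanged
  set.seed(66)
  x <- rnorm(500); y <- x + rnorm(500); z <- rnorm(500)
  raw <- cor(x, y, method = "spearman")
  expect_lt(abs(partial_spearman(x, y, z)$partial_rho - raw), 0.05)
  expect_error(partial_spearman(x[1:3], y[1:3], z[1:3]), "at least 4")
  expect_error(partial_spearman(x, y, rep(1, 500)), "non-constant")
})

test_that("co-expression modules recover planted blocks deterministically", {
  set.seed(67)
  base1 <- rnorm(20); base2 <- rnorm(20)
  expr <- rbind(a1 = base1, a2 = base1 * 2 + 5, a3 = base1 * 0.5,
                b1 = base2, b2 = base2 * 3 - 1)
  mod <- coexpression_modules(expr, k = 2)
  expect_equal(unname(mod[c("a1", "a2", "a3")]), rep(1, 3))
  expect_equal(unname(mod[c("b1", "b2")]), rep(2, 2))
  # k = number of genes: all singleton modules
  expect_equal(sort(unname(coexpression_modules(expr, k = 5))), 1:5)
  # invariant to input row order (identical assignment, not relabeled)
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(coexpression_modules(expr[perm, ], k = 2), mod,
               ignore_attr = TRUE)
  expect_error(coexpression_modules(expr, k = 9), "exceeds")
  # linkage heights match a brute-force complete-linkage agglomeration
  prof <- t(scale(t(expr)))
  d <- as.matrix(dist(prof))
  brute_heights <- local({
    groups <- as.list(rownames(prof))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        h <- max(d[groups[[i]], groups[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
      heights <- c(heights, best[1])
      groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
      groups[[best[3]]] <- NULL
    }
    heights
  })
  expect_equal(attr(coexpression_modules(expr, k = 2), "tree")$height,
               brute_heights, tolerance = 1e-12)
})

test_that("variance partitioning behaves at the two extremes", {
  meta <- seg_fixture()$segments$segment_meta
  # expression fully determined by tissue: biological fraction ~ 1
  set.seed(68)
  pattern <- matrix(rnorm(100 * 2), 100, 2)
  expr_t <- pattern[, as.integer(factor(meta$tissue))]
  expr_t <- expr_t + matrix(rnorm(length(expr_t), 0, 1e-3), nrow(expr_t))
  rownames(expr_t) <- sprintf("g%03d", 1:100)
  vp <- variance_partition(expr_t, meta)
  expect_gt(vp$biological, 0.99)
  # pure noise: both fractions stay small at 60 segments x 200 genes
  noise <- matrix(rnorm(200 * 60), 200, 60,
                  dimnames = list(sprintf("g%03d", 1:200), meta$segment_id))
  vp0 <- variance_partition(noise, meta)
  expect_lt(vp0$biological, 0.1)
  expect_lt(vp0$batch, 0.1)
  # nested slide design triggers the confounding warning
  meta2 <- meta
  meta2$slide <- ifelse(meta2$tissue == "EuE", "S1", "S2")
  expect_warning(variance_partition(noise, meta2), "nested")
})

test_that("the immune segment score is the marker-set mean", {
  seg <- seg_fixture()$segments
  sn <- q3_normalize(seg)
  ln <- log2(sn$normalized + 1)
  s <- immune_score_segments(ln)
  markers <- c("CD68", "CD3D", "CD3E", "PTPRC", "CD4", "CD8A")
  expect_equal(s, colMeans(ln[markers, ]), tolerance = 1e-12)
})
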