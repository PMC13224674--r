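test_that("pseudo-bulk aggregation yields one sample per patient-tissue", {
  sim <- sim_fixture()
  pb <- aggregate_pseudobulk(sim$cells)
  expect_equal(ncol(pb$counts), 24)  # 3 + 9 + 8 + 4 patients
  expect_equal(as.vector(table(pb$sample_meta$group)[c("Ctrl", "EuE", "EcP", "EcO")]),
               c(3L, 9L, 8L, 4L))
  # aggregation conserves total counts
  expect_equal(sum(pb$counts), sum(sim$cells$counts))
  # deterministic sample order: by group then patient
  expect_equal(pb$sample_meta$sample,
               pb$sample_meta$sample[order(pb$sample_meta$group,
                                           pb$sample_meta$patient)])
})

test_that("aggregation equals a brute-force per-gene sum", {
  m <- tiny_cells()
  pb <- aggregate_pseudobulk(m)
  for (s in pb$sample_meta$sample) {
    cells <- which(m$cell_meta$patient == pb$sample_meta$patient[
      pb$sample_meta$sample == s])
    brute <- rowSums(as.matrix(m$counts[, cells, drop = FALSE]))
    expect_equal(pb$counts[, s], brute)
  }
  # one cell per sample: the column equals that cell's counts
  one <- cell_matrix(
    matrix(c(3, 1, 0, 7), 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2"))),
    data.frame(cell_id = c("c1", "c2"), group = c("A", "B"),
               patient = c("A_P1", "B_P1"), cell_type = "T cells",
               n_genes_detected = 2L, n_umi = 10L, mito_fraction = 0))
  pb1 <- aggregate_pseudobulk(one)
  expect_equal(unname(pb1$counts[, "A_P1"]), c(3, 1))
  expect_equal(unname(pb1$counts[, "B_P1"]), c(0, 7))
})

test_that("low-expression filtering keeps replicated signal only", {
  counts <- rbind(
    lonely = c(12, rep(0, 23)),        # >= 10 in a single sample
    silent = rep(0, 24),               # all zero
    steady = rep(c(11, 0), 12),        # >= 10 in 12 samples
    weak   = rep(9, 24))               # never reaches 10
  colnames(counts) <- sprintf("s%02d", 1:24)
  pb <- structure(list(counts = counts,
                       sample_meta = data.frame(
                         sample = colnames(counts),
                         patient = colnames(counts),
                         group = rep(c("A", "B"), each = 12)),
                       size_factors = NULL),
                  class = "pseudobulk")
  kept <- rownames(filter_low_expression(pb)$counts)
  expect_identical(kept, "steady")
  # brute-force predicate scan on random input
  set.seed(6)
  rnd <- random_counts(80, 10, lambda = 4)
  pb2 <- pb; pb2$counts <- rnd
  pb2$sample_meta <- data.frame(sample = colnames(rnd),
                                patient = colnames(rnd), group = "A")
  kept2 <- rownames(filter_low_expression(pb2, min_count = 5,
                                          min_samples = 2)$counts)
  brute <- rownames(rnd)[vapply(seq_len(nrow(rnd)), function(i)
    sum(rnd[i, ] >= 5) >= 2, logical(1))]
  expect_identical(kept2, brute)
})

test_that("size factors follow the median-of-ratios construction", {
  counts <- random_counts(100, 6, lambda = 20)
  # identical samples: all factors 1
  same <- counts[, rep(1, 4)]
  colnames(same) <- paste0("s", 1:4)
  expect_equal(unname(size_factors(same)), rep(1, 4))
  # doubling one sample doubles its factor relative to the original
  doubled <- cbind(counts, dup = counts[, 1] * 2)
  sf <- size_factors(doubled)
  expect_equal(unname(sf["dup"] / sf[1]), 2, tolerance = 1e-12)
  # independent straightforward reimplementation (log-space median, the
  # same convention DESeq2 uses for the ratio median)
  set.seed(19)
  for (rep in 1:20) {
    m <- random_counts(60, 5, lambda = 15)
    ok <- apply(m > 0, 1, all)
    ref <- exp(rowMeans(log(m[ok, ])))
    brute <- numeric(ncol(m))
    for (j in seq_len(ncol(m)))
      brute[j] <- exp(median(log(m[ok, j] / ref)))
    brute <- brute / exp(mean(log(brute)))
    expect_equal(unname(size_factors(m)), unname(brute), tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  m <- random_counts(200, 8, lambda = 30)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))  # same geometric-mean gauge
  expect_equal(unname(size_factors(m)), unname(theirs), tolerance = 1e-8)
})

test_that("size factors are scale-equivariant with a fallback path", {
  m <- random_counts(50, 4, lambda = 10)
  sf <- size_factors(m)
  sf2 <- size_factors(m * 3)  # global scaling cancels in the gauge
  expect_equal(sf, sf2, tolerance = 1e-12)
  sparse <- m
  sparse[cbind(seq_len(nrow(sparse)),
               rep_len(seq_len(ncol(sparse)), nrow(sparse)))] <- 0
  expect_warning(size_factors(sparse), "total-count")
})

test_that("the NB Wald fit matches a fixed-theta GLM oracle", {
  skip_if_not_installed("MASS")
  set.seed(33)
  n1 <- 6; n2 <- 4
  sf <- exp(rnorm(n1 + n2, 0, 0.2))
  grp <- rep(c("A", "B"), c(n1, n2))
  counts <- matrix(rnbinom((n1 + n2) * 40, mu = rep(80 * sf, each = 40),
                           size = 1 / 0.15), 40)
  dimnames(counts) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:(n1 + n2)))
  pb <- structure(list(counts = counts,
                       sample_meta = data.frame(sample = colnames(counts),
                                                patient = colnames(counts),
                                                group = grp),
                       size_factors = setNames(sf, colnames(counts))),
                  class = "pseudobulk")
  de <- nb_wald_de(pb, "A", "B")
  x <- as.numeric(grp == "A")
  for (i in sample(which(de$converged), 10)) {
    disp <- nichecompare:::moment_dispersion(
      counts[i, ] / sf, sf, list(which(x == 1), which(x == 0)))
    fit <- glm(counts[i, ] ~ x + offset(log(sf)),
               family = MASS::negative.binomial(theta = 1 / disp))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(de$log2fc[i], unname(co["x", "Estimate"]) / log(2),
                 tolerance = 1e-5)
    expect_equal(de$se[i], unname(co["x", "Std. Error"]) / log(2),
                 tolerance = 1e-4)
  }
})

test_that("swapping the groups negates log2fc and preserves p", {
  sim <- sim_fixture()
  pb <- filter_low_expression(aggregate_pseudobulk(sim$cells))
  de_ab <- nb_wald_de(pb, "EcP", "Ctrl")
  de_ba <- nb_wald_de(pb, "Ctrl", "EcP")
  ok <- de_ab$converged & de_ba$converged
  expect_gt(mean(ok), 0.95)
  expect_equal(de_ab$log2fc[ok], -de_ba$log2fc[ok], tolerance = 1e-6)
  expect_equal(de_ab$p[ok], de_ba$p[ok], tolerance = 1e-6)
})

test_that("planted fold changes reach significance, null genes do not", {
  sim <- sim_fixture()
  pb <- filter_low_expression(aggregate_pseudobulk(sim$cells))
  de <- nb_wald_de(pb, "EcO", "Ctrl")
  sig <- significant_genes(de)
  # most of the strongly planted smooth-muscle program is detected even at
  # this desk scale (4 vs 3 patients); each estimate sits within its own
  # sampling band around the planted effect
  sm <- c(MYH11 = 3.87, ACTA2 = 2.68, DES = 3.59, TAGLN = 3.00)
  expect_gte(sum(names(sm) %in% sig), 3)
  idx <- match(names(sm), de$gene)
  expect_true(all(abs(de$log2fc[idx] - sm) < pmax(4 * de$se[idx], 1)))
  # background genes are rarely called
  bg <- grepl("^G\\d", de$gene)
  expect_lt(mean(de$significant[bg]), 0.02)
})

test_that("significant_genes applies the stored thresholds verbatim", {
  de <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               log2fc = c(3, 0.5, -2, 2),
               q = c(0.001, 0.001, 0.04, 0.2),
               significant = c(TRUE, FALSE, TRUE, FALSE)),
    class = c("de_result", "data.frame"))
  expect_equal(significant_genes(de), c("a", "c"))
  de$significant <- rep(FALSE, 4)
  expect_equal(significant_genes(de), character(0))
  # brute-force filter on a real result
  sim <- sim_fixture()
  pb <- filter_low_expression(aggregate_pseudobulk(sim$cells))
  d <- nb_wald_de(pb, "EcP", "EcO")
  brute <- d$gene[!is.na(d$q) & d$q < attr(d, "alpha") &
                    abs(d$log2fc) > attr(d, "lfc_threshold")]
  expect_identical(significant_genes(d), brute)
})
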