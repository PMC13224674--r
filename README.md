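# nichecompare

Comparative single-cell and spatial transcriptomics of endometriosis lesion
niches.

Endometriosis presents as molecularly distinct lesion types: peritoneal
lesions (EcP) build a chemokine-driven, immune-rich ("immune-hot") niche,
while ovarian lesions (EcO) favor fibromuscular differentiation with sparse
immune infiltration ("immune-cold"). `nichecompare` implements the
statistical pipeline for making that comparison quantitative across a
single-cell atlas (four tissue groups — control endometrium `Ctrl`, eutopic
endometrium `EuE`, and the lesions `EcP`/`EcO` — with patient replication)
and segment-based spatial profiling sorted into macrophage, epithelial and
stromal compartments.

The package is aimed at analysts reproducing or extending this style of
integrative lesion-subtype analysis, and every statistical component is
exercised end-to-end on a built-in synthetic cohort with known ground truth.

## What it implements

* **QC and normalization** — strict cell filters (< 500 genes, < 1000 UMIs,
  > 25% mitochondrial), counts-per-10k log-normalization, segment detection
  filtering (> 30%), upper-quartile (Q3) segment scaling toward the
  geometric-mean target, and cross-platform gene harmonization
  (> 5 counts in > 10% of units on both platforms).
* **Two-step sparse-gene test** — for genes expressed in a small fraction
  of cells, separate inference for (i) the expressing-cell fraction via a
  pooled two-proportion z-test, `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))`,
  and (ii) expression intensity among expressors via Welch's t-test on log
  values of the geometric mean; the two p-values are reported separately
  with BH adjustment per family.
* **Pseudo-bulk NB Wald DE** — patient-level aggregation, median-of-ratios
  size factors, and a transparent per-gene negative-binomial GLM
  (log link, size-factor offset, moment dispersion, IRLS) with the Wald
  statistic referred to a residual-df t distribution; significance at
  `|log2FC| > 1` and BH `q < 0.05`.
* **Gene-set scores** — plain mean of log-normalized expression over a
  signature (smooth muscle, cytotoxicity, exhaustion, checkpoints, immune
  markers shipped), group summaries, and rank-based ROC AUC.
* **Spatial co-expression** — all-pairs Spearman with BH adjustment, the
  ligand-receptor screen (`rho > 0.7`, `q < 0.001`), partial Spearman
  correlation controlling a composite immune score
  (`rho_xy.z = (rho_xy - rho_xz rho_yz) / sqrt((1-rho_xz^2)(1-rho_yz^2))`),
  complete-linkage co-expression modules, and PCA-based variance
  partitioning into biological (tissue + compartment) and batch (slide)
  fractions.
* **Niche classification and reporting** — pathway-level network summaries
  and an explicit, reproducible immune-hot/immune-cold rule.
* **Synthetic data** — seeded generators for the cell atlas (NB background,
  patient-level biological effects, group-targeted programs, sparse
  expressor genes) and the 60-segment spatial design (planted variance
  shares, a Gaussian-copula ligand-receptor pair with an immune-content
  confounder), each returning a ground-truth table for recovery tests.

## Worked example

```r
library(nichecompare)

# 1. Simulate the cohort at desk scale (24 patients, 2000 genes) and QC it
sim <- simulate_cells(sim_config(seed = 2))
qc <- qc_filter_cells(sim$cells)
print(qc$report)
#>       n_input        n_kept removed_genes   removed_umi  removed_mito
#>         12000         11049           198           376           562
#> removed_total
#>           951

# 2. Expressing-cell fractions and the two-step test for a sparse chemokine
positive_cell_proportions(qc$cells, "CCL19")
#>   group k_positive n_total    fraction
#> 1  Ctrl          6    1369 0.004382761
#> 2   EuE         21    4113 0.005105762
#> 3   EcP         71    3714 0.019116855
#> 4   EcO          2    1853 0.001079331
counts <- as.matrix(qc$cells$counts[c("CCL19", "NNMT"), ])
sparse_gene_test_table(counts, qc$cells$cell_meta$group,
                       c("CCL19", "NNMT"), list(c("EcP", "Ctrl")))
#>    gene      frac1       frac2      p_frac intensity_ratio p_intensity
#> 1 CCL19 0.01911686 0.004382761 0.000136082        7.677604 0.001433892
#> 2  NNMT 0.24663436 0.273922571 0.047399133        1.004138 0.908540849

# 3. Patient-level pseudo-bulk differential expression (EcP vs Ctrl)
pb <- filter_low_expression(aggregate_pseudobulk(qc$cells))
de <- nb_wald_de(pb, "EcP", "Ctrl")
de[de$gene %in% c("CTLA4", "TIGIT", "CCL21"),
   c("gene", "log2fc", "se", "p", "q", "significant")]
#>     gene   log2fc        se            p           q significant
#> 8  CTLA4 2.360024 0.2756234 1.281110e-05 0.006405548        TRUE
#> 10 TIGIT 1.944442 0.2447391 2.338898e-05 0.009355590        TRUE
#> 18 CCL21 1.836929 0.2835987 1.144473e-04 0.028611814        TRUE

# 4. Spatial segments: Q3 normalization, LR screen, immune adjustment
seg <- simulate_segments(sim_config(seed = 2))
sn <- q3_normalize(qc_filter_segments(seg$segments))
ln <- log2(sn$normalized + 1)
rec <- spearman_matrix(ln, c("CCL19", "CCR7", "TGFB1", "TGFBR1", "CD68", "PTPRC"))
ligand_receptor_screen(rec, list(c("CCL19", "CCR7")))
#>   ligand receptor       rho            p            q  n passes_screen
#> 1  CCL19     CCR7 0.8285079 3.095252e-16 2.321439e-15 60          TRUE
ps <- partial_spearman(ln["CCL19", ], ln["CCR7", ], immune_score_segments(ln))
sprintf("partial rho = %.3f (p = %.3g)", ps$partial_rho, ps$p)
#> [1] "partial rho = 0.682 (p = 2.71e-09)"

# 5. Immune-hot / immune-cold classification
imm <- attr(composition_table(qc$cells), "immune")
chk <- group_score_summary(
  geneset_score(lognormalize(qc$cells), default_signatures()$immune_checkpoint),
  qc$cells$cell_meta$group)
classify_niche(setNames(imm$immune_fraction, imm$group),
               setNames(chk$mean, chk$group), reference = "Ctrl")
#>   group immune_fraction checkpoint_score          call
#> 1  Ctrl       0.2425128        0.2673420 indeterminate
#> 2   EuE       0.3420861        0.2456030 indeterminate
#> 3   EcP       0.4620355        0.7643832    immune-hot
#> 4   EcO       0.1516460        0.2256345   immune-cold
```

Reading the output: the QC report counts removals per criterion (a cell can
trip several). The simulated CCL19-like gene is expressed in 1.9% of EcP
cells versus 0.44% of control cells — a significant frequency shift — and,
among expressing cells, at a 7.7-fold higher intensity (the generator
planted 7.6-fold), with the two phenomena tested separately. The planted
peritoneal checkpoint program (CTLA4 at log2FC 2.30, TIGIT at 1.90) is
recovered at the patient level with calibrated uncertainty. In the spatial
segments, the planted ligand-receptor pair passes the co-expression screen
and retains a partial correlation of 0.68 after adjusting for immune
content, showing the association is not an immune-admixture artifact.
Finally, the lesion groups classify as immune-hot (EcP) and immune-cold
(EcO), with the intermediate tissues left indeterminate by design.

## Package layout

* `R/` — containers (`cell_matrix`, `segment_matrix`, `pseudobulk`),
  simulators, QC/normalization, the two-step test, pseudo-bulk DE, gene-set
  scoring, spatial correlation/cluster/variance tools, network and report
  helpers, Matrix-Market/CSV/GMT/JSON IO.
* `tests/testthat/` — unit and property tests per module (each statistic is
  checked against an independent brute-force oracle), plus the end-to-end
  calibration suite in `test-acceptance.R`.
* `vignettes/niche-methods.Rmd` — the methods vignette: model assumptions,
  parameter defaults and their rationale, what the synthetic cohort does
  and does not emulate, numerical conventions, and known limitations.
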