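---
title: "Methods: comparing immune and stromal niches across endometriosis subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing immune and stromal niches across endometriosis subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecompare)
```

## The analysis problem

Endometriosis lesions are heterogeneous: peritoneal lesions (EcP) tend to be
inflammatory and immune-rich, while ovarian lesions (EcO) are fibromuscular
and immune-sparse. `nichecompare` implements the statistical machinery for
comparing these niches across two data modalities: a single-cell RNA-seq
atlas spanning four tissue groups (control endometrium `Ctrl`, patient
eutopic endometrium `EuE`, and the two lesion types `EcP`, `EcO`, with
patient-level replication), and segment-based spatial profiling of lesion
tissue, where each region of interest is sorted into macrophage, epithelial
and stromal compartments.

Every statistical component is exercised end-to-end on synthetic data whose
generative structure mirrors the study design, so calibration and
parameter-recovery claims are testable without access to the original
accessions.

## Quality control and normalization

Cells are removed when they detect fewer than 500 genes, carry fewer than
1000 UMIs, or exceed 25% mitochondrial content (`qc_filter_cells()`).
Removal is strict: a cell exactly on a threshold is kept. These thresholds
are exposed through `qc_thresholds()` with those defaults.

Cell-level expression is log-normalized as `log(1 + 1e4 * count / total)`
(`lognormalize()`). The downstream statistics only require a monotone
log-scale normalization, so this standard counts-per-10k transform is used
rather than a variance-stabilizing model fit; positivity ("expression > 0")
is identical under any monotone transform and is therefore evaluated on raw
counts once, in `positive_cell_proportions()`.

Spatial segments are retained when their gene detection rate exceeds 30%
(`qc_filter_segments()`), then scaled by the upper-quartile (Q3) method
(`q3_normalize()`): each segment is multiplied by `target / Q3(segment)`,
where Q3 is the 75th percentile of the segment's positive counts and the
common target is the geometric mean of all segment Q3s. With that target
the normalization is idempotent and every normalized segment has an
identical upper quartile. Q3 is computed over positive counts only — on a
panel where most genes are detected this matches the platform convention,
and it keeps the statistic defined for sparse segments.

Cross-platform comparisons are restricted to genes detected on both
platforms: more than 5 counts in more than 10% of units, on each platform
separately (`harmonize_genes()`, strict inequalities on both conditions).

## The two-step test for sparsely expressed genes

For a gene expressed in a few percent of cells (the CCL19 situation),
comparing all cells between groups dilutes a real difference with zeros.
`two_step_sparse_test()` separates:

1. **Frequency**: the expressing-cell fractions are compared with a pooled
   two-proportion z-test (`two_proportion_ztest()`), no continuity
   correction, so `z^2` equals the 2x2 Pearson chi-square statistic.
2. **Intensity**: among expressors only, the geometric mean of expression
   is compared by Welch's t-test on natural-log values (`welch_t_log()`,
   Welch–Satterthwaite df). The log base cancels in both the statistic and
   the geometric-mean ratio.

The two p-values are reported separately, never combined; if a group has
fewer than two expressors, the intensity step is flagged not evaluable and
the frequency step still returns. Across genes,
`sparse_gene_test_table()` applies Benjamini–Hochberg adjustment to the two
steps as *separate families within each comparison*, because they answer
different questions and are reported as distinct quantities.

The frequency step's p-value is intrinsically discrete (it is a function of
two binomial counts). Its null distribution therefore cannot be exactly
uniform at any sample size; the test suite checks its type-I error at the
nominal level and its agreement with the exact finite-sample null law,
while the continuous intensity p-value is checked for uniformity directly.

## Pseudo-bulk negative-binomial Wald test

Patient-level inference aggregates cell counts per patient–tissue sample
(`aggregate_pseudobulk()`; the default study design yields 24 samples:
3/9/8/4 in Ctrl/EuE/EcP/EcO). Genes without at least 10 counts in at least
3 samples are dropped (`filter_low_expression()`; both parameters exposed,
since a stricter "row sum" reading is also defensible). Size factors are
median-of-ratios with the ratio median taken in log space and the factors
gauged to geometric mean 1 (`size_factors()`), matching the convention of
the count-model DE packages.

`nb_wald_de()` fits, per gene, an NB GLM with log link, `log(size factor)`
offset and one group coefficient, by iteratively reweighted least squares.
The gene's dispersion is a method-of-moments estimate on normalized counts,
pooled across the two groups and floored at 1e-8. Two numerical choices
matter:

* **Reference distribution.** The Wald statistic is referred to a *t*
  distribution with residual degrees of freedom (samples − 2), not a
  standard normal. With per-gene plug-in dispersions at 4-vs-4 replicates a
  normal reference is badly anti-conservative (empirical null type-I
  ~0.10 at nominal 0.05 in our simulations); the residual-df t reference
  restores calibration (0.045–0.057 across regimes), in line with
  small-sample quasi-likelihood practice. This is deliberately more
  conservative than shrinkage-based pipelines and makes the package's
  fold-change significance calls transparent and oracle-checkable.
* **No shrinkage.** Neither dispersions nor fold changes are shrunk, so
  estimates from reference pipelines that shrink are approximate
  comparators only.

Genes with a zero group mean get a pseudo-count fold change and no p-value;
non-converged fits are flagged. `significant_genes()` applies
`|log2FC| > 1` and BH-adjusted `p < 0.05` by default.

## Gene-set scores, ROC, and niche classification

`geneset_score()` is the unweighted mean of (log-)normalized expression of
the set's present genes per cell or segment — a plain mean, with no
control-pool background correction, because the downstream comparisons are
within-dataset group contrasts. The shipped signatures
(`default_signatures()`) are the printed ones: smooth muscle
{MYH11, ACTA2, DES, TAGLN}, cytotoxicity {GZMB, PRF1, GNLY}, exhaustion
{CTLA4, PDCD1, LAG3, HAVCR2, TIGIT}, segment immune markers
{CD68, CD3D, CD3E, PTPRC, CD4, CD8A}. The broader pathway sets (immune
response, angiogenesis, hormone response, ECM) are small non-authoritative
defaults assembled from genes the analysis names; curated GMT files can be
supplied through `read_gmt()`.

`roc_auc()` is the rank (Mann–Whitney) AUC with ties counted one half,
hence invariant under monotone transforms.

`classify_niche()` operationalizes the qualitative immune-hot/immune-cold
dichotomy with explicit thresholds: hot requires an immune cell fraction of
at least 0.30 *and* a checkpoint score above the reference group's mean;
cold requires at most 0.20 and a score at or below the reference mean;
anything else is indeterminate. The thresholds are package parameters — a
design decision, not an estimate of the original authors' implicit rule —
chosen to sit comfortably between the observed lesion immune fractions
(46.3% vs 15.3%) while leaving a deliberate indeterminate band.

## Spatial co-expression and the confounding adjustment

`spearman_matrix()` computes all-pairs Spearman correlations on normalized
segment expression, with p-values from the t approximation at `n − 2` df
(adequate at n = 60; an exact-permutation check is part of the test suite's
oracles) and BH adjustment within the tested family. A ligand–receptor
pair is declared spatially co-expressed when `rho > 0.7` and BH-adjusted
`p < 0.001` (`ligand_receptor_screen()`, thresholds configurable).

Because segments mix cell types, a ligand–receptor correlation can be
driven by immune content rather than co-regulation. `partial_spearman()`
rank-transforms the two genes and the composite immune score
(`immune_score_segments()`, the mean of the six immune markers) and applies
the first-order partial correlation formula, with `n − 3` df. Controlling
the single composite score — not six markers separately — mirrors how the
adjustment is constructed in the source analysis and keeps the residual df
interpretable at n = 60.

`coexpression_modules()` clusters standardized gene profiles by complete
linkage on Euclidean distance and cuts at `k` modules; genes are processed
in lexicographic order and modules renumbered by first appearance, making
the assignment invariant to input order. `variance_partition()` scales
genes, takes a PCA over segments, and reports
`sum(f_i * R^2_i)` where `R^2_i` comes from regressing each component on
`tissue + compartment` (biological) and, separately, on `slide` (batch).
The two fractions are from separate regressions — they are reported that
way and need not add to at most one; slide designs nested in tissue are
flagged as confounded.

## The synthetic-data generator

`simulate_cells()` draws negative-binomial background counts (shared
dispersion 0.5, gene means log-uniform on [0.05, 3] per cell), a log-normal
per-cell depth factor (sd 0.3), and a log-normal per-patient, per-gene
biological effect (sd 0.3). The patient effect is what makes pseudo-bulk
inference meaningful: summing cells within a patient yields NB-distributed
sample counts with dispersion roughly 0.09, a typical bulk biological
variability, and without it pseudo-bulk counts would be unrealistically
close to Poisson. Group-targeted programs multiply background means by
`2^log2fc` in their target group; sparse genes are generated purely by the
expressor mechanism — each cell expresses with its group's probability, and
expressors draw a log-normal intensity whose geometric mean is the
configured value. QC metadata (detected genes, UMIs, mitochondrial
fraction) describe the whole-transcriptome scale, with a planted 5%
low-quality fraction, and are simulated alongside the down-sampled gene
panel rather than recomputed from it.

Defaults are the study conditions: 3/9/8/4 patients, immune content
23.9/33.9/46.3/15.3%, smooth muscle at 39.8% of EcO, a CCL19-like gene at
expressing fractions 0.25/1.61/0.06% (Ctrl/EcP/EcO) with a 7.6-fold
expressor intensity in EcP, and the printed smooth-muscle/checkpoint
effect sizes. The desk scale (500 cells/patient, 2000 genes) keeps a full
run under ten seconds; all sizes are configuration, not code.

`simulate_segments()` produces 60 segments (30 per tissue, three
compartments, slides 24/24/12 interleaved across tissues so slide is not
nested in tissue). Background genes follow a log-normal–Poisson model whose
log-scale variance is split 0.60 / 0.12 / 0.28 between additive
tissue-plus-compartment structure, slide, and residual noise; pattern rows
are standardized so the planted shares are exact. Biological effects are
additive in tissue and compartment because the variance-partition estimator
regresses on the additive model; planting interactions the model cannot
represent would conflate generator and estimator. The ligand–receptor pair
and the immune markers are generated through a Gaussian copula
(`qnbinom(pnorm(z))` on NB marginals): the pair loads on a latent niche
factor and on a latent immune-content factor, so the marginal rank
correlation hits its target (Pearson equivalent `2*sin(pi*rho/6)`,
partitioned as direct² + confounder²), while the immune markers load on the
same immune factor and make the composite immune score an effective
adjustment covariate. With the defaults (marginal Spearman 0.87, confounder
loading 0.75), the implied partial correlation after immune adjustment is
about 0.71. Note that the *sample* Spearman at n = 60 sits near 0.86 even
under a perfect copula — the estimator's finite-sample expectation, not an
attenuation artifact.

What the generator does **not** emulate: doublets, ambient RNA,
gene–gene covariance beyond the configured programs, patient-level
variation in expressing *fractions* (fractions are i.i.d. Bernoulli so the
binomial recovery oracles are exact), and segment-level cell-type
deconvolution. Passing tests therefore demonstrate calibration and
recovery under the assumed generative structure, not robustness to every
artifact of real data.

## Problem sizes and numerical conventions

The test suite and the acceptance script use: 10,000 replicates for null
calibration of the two-step test at 2,000 cells per group and base
expressing fraction 0.02; 2,000 genes at 4-vs-4 samples for the NB null;
200 planted genes at 8-vs-4 samples for fold-change recovery; 200 seeded
replicates each for the confounder-removal and screen-power properties;
and one 2,000-gene, 60-segment dataset for variance-partition recovery.
Dispersions are floored at 1e-8; IRLS runs at most 50 iterations to a
1e-8 coefficient tolerance; means are clamped to [1e-10, 1e12] during
fitting; BH families are always stated alongside the adjusted values.

## Known limitations

* The NB Wald test is transparent but unshrunk; at 3–4 replicates its
  per-gene estimates are noisy and weak effects (the TAGLN-sized ones) can
  miss significance at desk scale.
* The hot/cold classification is an operational rule; its thresholds are
  package parameters with no claim of optimality.
* Q3 normalization assumes segments share a broadly similar expression
  ceiling; it is not appropriate for panels dominated by
  compartment-exclusive genes.
* The pathway defaults beyond the printed signatures are placeholders for
  curated gene sets.
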