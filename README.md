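# tmecorr

Spatially resolved single-cell analysis of multiplexed tissue imaging,
built around the question of how purinergic signaling is organized in the
glioma tumor microenvironment: CD73 (the adenosine-producing
ecto-5′-nucleotidase) sits mostly on tumor cells, CD39 (the upstream
ATP/ADP-hydrolyzing ectonucleotidase) mostly on myeloid cells, and the
two-step pathway only works where those populations meet. `tmecorr`
provides the statistical machinery to measure that meeting from segmented
CyCIF cell tables, for imaging scientists and computational biologists
working with tissue-microarray cohorts.

## What it computes

The core statistic is a k-nearest-neighbor spatial cross-correlation. For
cell types A and B and variables U, V (marker log-intensities or binary
type indicators),

```
r(k) = cor( U on A-cells , V on their k-th nearest B-neighbor ),  k = 1..kmax
```

indexed by the mean pair distance d̄(k) in µm, and summarized per core by
the two-parameter exponential fit

```
C(d) = c * exp(b * d)
```

where `c` is the correlation strength at zero distance and `b` the decay
rate (per µm). If the 95% CI of `c` contains 0 the core is insignificant
and its effective strength is 0; a patient is "high interaction" only if
all of their cores are significant. The CI is a parametric bootstrap
under the fitted model — replicate latent-field realizations at the
actual cell positions, pushed through the fixed neighbor structure and
refit — because curve points are strongly dependent and part of the
uncertainty is realization variance of the spatial process itself; see
the methods vignette for the reasoning and the fallback constructions.

Around this sit the supporting stages: single-cell QC (zero-DNA removal,
DNA coefficient-of-variation filter at mean + 3 SD, GMM autofluorescence
filter), GMM marker gating with hierarchical lineage assignment (Tumor /
Myeloid / Lymphoid / Endothelial / Other), LDA cellular-neighborhood
topics over 10-nearest-neighbor token documents, gene-signature scoring
(`log2(1 + mean expression)`) with quartile-stratified Wilcoxon
comparisons, and a synthetic-tissue generator that plants spatial
correlation of known strength `rho` and decay length `ell` through an
exponential-covariance Gaussian field, so the whole pipeline can be
validated against ground truth.

## Worked example

```r
library(tmecorr)

# a synthetic 1 mm core: ~2500 cells, Tumor-CD73 x Myeloid-CD39 coupling
# with strength 0.6 decaying over 50 um, plus planted QC defects
sim <- simulate_tissue(tissue_sim_config(seed = 42))

qc    <- qc_pipeline(sim$table, af_markers = "AF1")
print(qc$report)
#> qc_report: 2515 cells in; removed 0 zero-DNA, 50 high-CV (thr 0.6341), 126 high-AF; 2339 retained

typed <- assign_cell_types(qc$table)
print(typed)
#> cell_type_call: Tumor=1158, Myeloid=658, Lymphoid=96, Endothelial=112, Other=315

q   <- correlation_query("Tumor", "Myeloid", "CD73", "CD39", kmax = 100)
cur <- correlation_curve(qc$table, typed, q)
fit <- fit_exponential(cur)
print(fit)
#> exponential_fit: c = 0.4506 [0.3092, 0.5919], b = -0.01317 /um, significant (100 points)
```

Reading the output: the QC report reconciles exactly (2515 = 2339
retained + removals, each removed cell with one primary reason; the 50
high-CV and 126 high-AF removals are exactly the planted defects); typing
recovers the planted lineage of every retained cell in this example; the
fit says tumor-cell CD73 and nearby myeloid-cell CD39 log-intensities
correlate with strength ≈ 0.45 at zero distance in this realization
(planted ensemble value 0.6, single-core realizations scatter around it),
decaying with length 1/0.0132 ≈ 76 µm, and the interval excludes 0, so
this core counts as a significant tumor–myeloid purinergic interaction.
Per-patient classification then follows with `fit_cores()` and
`interaction_class()`.

A command-line interface wraps the same steps
(`inst/cli/tmecorr simulate|qc|type|spatialcorr|topics|signatures`), each
subcommand seeded and writing CSV/JSON artifacts.

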