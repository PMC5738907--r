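---
title: "Separating tumor-associated macrophages by ontogeny: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating tumor-associated macrophages by ontogeny: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tamont)
```

## The problem

Gliomas are infiltrated by tumor-associated macrophages (TAMs) of two
developmental origins: brain-resident microglia, seeded during early
development, and bone marrow-derived macrophages (BMDM) that differentiate
from blood monocytes after crossing the blood-brain barrier. The two
lineages are hard to separate in malignant tissue because most classical
macrophage markers are shared. `tamont` implements a computational route to
separate them from single-cell RNA-seq, derive a lineage gene signature,
and carry that signature into bulk cohorts and regional expression atlases.

The pipeline has four stages:

1. **Cell annotation.** Quality filtering, CPM normalization, and
   classification of each cell as TAM, neoplastic, or unassigned using
   marker expression, expressed somatic mutations, and copy-number
   evidence.
2. **Signature derivation.** Feature selection to murine-homologue
   candidates, `log2(CPM/10 + 1)` transform, per-platform z-scoring,
   PCA with Varimax rotation, a two-component Gaussian mixture on PC1, and
   loading-threshold extraction with an enrichment-based lineage
   orientation.
3. **Validation.** Multi-table factor analysis (MFA) across capture
   platforms, consensus clustering, and Matthews correlation between
   independent partitions.
4. **Propagation.** Ontogeny scores in bulk cohorts (subtype comparison by
   Tukey's range test, median-split Cox survival adjusted for age and
   gender) and per-structure enrichment in regional atlases.

## Model and assumptions

**Cell classification** assumes that neoplastic cells, and only neoplastic
cells, carry clonal expressed somatic variants and broad copy-number
changes. A cell is neoplastic if it has at least one variant with
`alt_count >= 2` (two supporting reads guard against single-read errors),
or if its CNV evidence is strong: the mean absolute per-segment score
exceeds `tau = 0.5` *and* the score signs agree with the called
amplification/deletion directions in at least `kappa = 2/3` of scored
segments. The per-segment score is a control-referenced z-score: segment
genes' log expression centered and scaled by non-malignant control cells,
with the control SD floored at 0.1 so low-variance genes cannot blow up the
ratio. Non-neoplastic cells are TAMs when their mean log marker expression
exceeds 1.0 on the `log2(CPM/10 + 1)` scale. The marker panel (default
PTPRC, ITGAM, AIF1, CD14, CSF1R, HLA-DRA) is a configurable input, not a
constant of the method.

**Signature derivation** assumes lineage identity is the dominant axis of
variation among TAMs once the feature space is restricted to candidates
with prior lineage evidence — homologues of genes differentially expressed
between BMDM and microglial TAMs in two murine glioma models, filtered to
mean CPM strictly above 1 in the human TAMs. PCA is run on per-platform
z-scores so that platform-level location and scale differences cannot
masquerade as biology; the rotation stage then sparsifies loadings.
Loadings are kept on the correlation scale (unit eigenvectors scaled by the
component SD), so a gene's PC1 loading is its correlation with the
component; Varimax is applied to these scaled loadings with Kaiser
normalization. This matters for the extraction threshold: with unit-norm
eigenvectors over a ~240-gene pool, no planted subset of ~66 genes could
exceed an absolute loading of 0.2 (the squared loadings must sum to one),
whereas correlation-scale loadings make the 0.2 threshold a meaningful
"strongly loading" cut. The raw eigenvectors remain available in
`$unrotated$rotation`.

The **two-component Gaussian mixture** on PC1 assumes bimodality of the
lineage axis. The overlap statistic — the integral of the pointwise minimum
of the two weighted component densities — quantifies how cleanly the
populations separate; it is 0.5 for coincident equal-weight components and
near 0 for well-separated ones.

The **lineage orientation** of the axis is never taken from a sign
convention. A two-sided Fisher's exact test on the 2x2 table of loading
sign against murine lineage (among the genes passing the threshold) decides
which direction is blood-derived; an ambiguous orientation (p > 0.1) is an
error rather than a silent guess.

**Survival propagation** assumes proportional hazards for the high/low
score strata. The median split sends ties to the low stratum (the boundary
is a design choice; the method's description does not fix a tie rule).
Tied event times use the Efron approximation, appropriate for
registry-scale data where ties are common. Gender enters as a single
indicator with the first factor level as reference.

## Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `min_genes`, `min_reads` | 800, 50 000 | genes, reads per cell | QC floor; boundaries inclusive. Total counts stand in for aligned reads when no alignment metadata exists (a monotone proxy). |
| `min_mean_cpm` | 1 | CPM | strict `>`; removes candidates without robust expression |
| `threshold` | 0.2 | correlation-scale loading | "strongly loading" cut for the signature |
| `n_components` | 10 | components | retained before rotation; only PC1 is consumed downstream |
| `cnv_tau`, `cnv_kappa` | 0.5, 2/3 | z units, fraction | CNV evidence strength and direction concordance |
| `min_alt` | 2 | reads | variant support for an expressed mutation |
| `marker_threshold` | 1.0 | log2(CPM/10 + 1) | TAM marker positivity |
| `detect_threshold` | 0 | CPM | a gene is "expressed" when CPM > 0 (presence semantics; configurable) |

## What the synthetic data emulate — and what they do not

The generator produces every input the pipeline consumes, with ground
truth: a murine lineage table (dual-model differential genes with lineage
labels), a mouse-to-human homology map (with homologues that fail the
expression filter and homologues absent from the matrix, so the feature
selection is genuinely exercised), a dual-platform single-cell cohort,
bulk cohorts with survival, and a regional atlas.

Counts are negative binomial (dispersion 0.4) around per-class expression
profiles scaled by per-cell log-normal library sizes, with per-platform
Bernoulli detection thinning — the minimal model reproducing the depth and
detection differences between a full-length microfluidic capture ("C1") and
a plate-based protocol ("SS2"). Default platform settings: detection 0.60
vs 0.75, library meanlog log(3e5) vs log(4e5), sdlog 0.9 vs 1.0. The
spread of library sizes produces a realistic QC failure fraction without a
dedicated "bad cell" class.

Planted lineage structure: 66 of 237 candidate genes are truly
lineage-specific with mean absolute log2 fold-change 4.0 between TAM
lineages (per-gene effects jittered by ±25%). The magnitude reflects how
the established lineage markers behave — genes like the purinergic
receptors used to isolate microglia are close to on/off between lineages
rather than modestly shifted — and the candidate pool is drawn
well-expressed (lognormal relative abundance, meanlog 2.5), as marker
panels are. With ~3000 TAMs this regime reproduces the qualitative
structure the method targets: a strongly bimodal PC1 with mixture overlap
well under 5%.

Neoplastic cells (25% of cells) carry four planted CNV segments
(contiguous blocks of ten 1 Mb-spaced genes, alternating amplification at
fold 2 and deletion at fold 1/2), silenced macrophage markers, and twelve
clonal SNVs each observed with probability 0.6 per cell (alt count
2 + Poisson(2)). TAM cells only ever show reference reads.

Bulk samples mix the two lineage profiles through a latent blood content
uniform on [0, 1]; each signature gene moves by `effect_amp = 1` log2 unit
across the full content range, with per-gene measurement noise
`noise_sd = 0.15` — the precision expected of well-expressed genes in
bulk RNA-seq. Hazards multiply by the planted hazard ratio for the top
half of true content, with age (+2%/year) and male (+10%) effects;
censoring is independent exponential calibrated to the requested rate.
The regional atlas shifts blood-signature genes upward by 2 z-units in
vascular and peri-necrotic structures and microglial genes in the leading
edge and infiltrated white matter, with a shared per-tumor intercept
(SD 0.2) acknowledging that structures from one tumor are not independent.

Not emulated: read-level data, doublets, ambient RNA, cell-cycle
structure, batch chemistry beyond the two-platform depth/detection model,
and any continuum of intermediate lineage states — the planted truth is
binary. Passing tests therefore show that the pipeline recovers a clean
planted dichotomy under realistic noise; they cannot show how the method
behaves when lineage identity is genuinely graded, when markers are
regulated by microenvironment rather than origin, or under platform
artifacts outside the location/scale family absorbed by z-scoring.

## Numerical choices

* **PCA/Varimax:** components ordered by post-rotation sum of squared
  loadings; each loading column flipped so its largest-magnitude entry is
  positive (orientation to lineage is decided by the enrichment test, not
  by this convention). Varimax uses Kaiser normalization, tolerance 1e-9.
  Rank-deficient inputs reduce the component count with a warning.
* **GMM:** EM with 10 restarts (quantile-seeded, then k-means-seeded),
  log-likelihood tolerance 1e-8, at most 500 iterations, variance floor
  1e-6 against collapse; best likelihood kept; overlap by trapezoidal
  quadrature on 20 001 points over the means ± 8 SD.
* **Dispersion estimation (differential expression):** method-of-moments
  within groups, pooled; a parametric trend `a0 + a1/mean` fitted across
  genes; estimates below the trend are shrunk halfway up to it, while
  estimates above the trend are kept — shrinking them down would
  understate the Wald SE and inflate the extreme tail of the null. The
  Wald statistic uses per-group empirical variances floored by the trend
  prediction and a t reference with `n1 + n0 - 2` degrees of freedom.
  Size factors are median-of-ratios with a positive-count geometric-mean
  reference and a total-count fallback for degenerate cells.
* **Consensus clustering:** Euclidean, Pearson and Spearman distances;
  two transforms each (leading principal components of the distance
  matrix; eigenvectors of the symmetric normalized graph Laplacian of
  `exp(-D/max(D))`, taken from the small-eigenvalue end); k-means
  (10 restarts) over a reduced grid of 4%, 5%, 6%, 7% of n leading
  dimensions; the mean binary co-clustering matrix is cut by
  complete-linkage hierarchical clustering at k. Above `max_cells = 800`
  cells, the consensus is built on a random training subsample and the
  remaining cells are assigned to the nearest training-cluster centroid —
  the same training/assignment split that consensus methods use at scale,
  and what keeps the O(n^2) eigendecompositions tractable.
* **Fisher's exact test:** two-sided by summing table probabilities not
  exceeding the observed one; p clamped to 1 against floating-point
  overshoot. Odds ratios are the sample `(ad)/(bc)` with the
  Haldane-Anscombe +0.5 on all cells when any count is zero.
* **MFA:** each table divided by its first singular value, concatenated
  over cells, PCA on the concatenation; a table's partial inertia is the
  sum of squared scores of its cells over all retained components (the
  component count is a free choice; all retained components is the one
  that makes the duplicated-table ratio exactly 1). A single table
  degenerates to its plain PCA.
* **Seeds:** one master seed per run; stage seeds derive from it by fixed
  offsets, so adding a stage never perturbs existing streams. Every
  generator restores the caller's RNG state.

## Design choices on open points

* The per-cell CNV quantification of exome-informed segment calls uses a
  plain per-segment mean of control-referenced z-scores; no genome
  smoothing or windowing is applied. This keeps the score interpretable
  and the control the only reference.
* QC thresholds are applied uniformly to both platforms; both defaults
  are inclusive (`>=`).
* The regional enrichment stage adds a formal one-vs-rest rank-sum test
  with BH correction to what is otherwise a descriptive ranking of
  structure-level mean scores; the output carries a caveat that samples
  sharing a tumor are treated as independent by the test even though the
  generator plants a tumor random effect.
* Matthews correlation between partitions is maximized over the two label
  matchings, since cluster labels are arbitrary.
* Whether bulk scores are z-scored before or after the median split is
  immaterial to the split (z-scoring is monotone); scores are z-scored
  across the cohort and the split taken on the z-scores.

## Problem sizes used by the test suite

The acceptance checks run the full pipeline on ten replicate cohorts of
19 samples with 240 cells each (~3000 TAMs passing QC per cohort, 237
candidates, 66 planted signature genes), 200 bulk cohorts of n = 363 for
survival recovery plus 50 null cohorts, 20-replicate null and recovery
atlases, and 20 + 10 replicates for differential-expression calibration
and power at 100 cells per group. These sizes keep every property estimate
stable while the whole suite completes in a few minutes on one CPU.

## Known limitations

* The signature extraction assumes a single dominant lineage axis; a
  second strong axis (e.g. activation state) that correlates with
  platform or sample could compete with PC1 after rotation.
* The classifier's CNV route needs a trustworthy control population;
  the pipeline bootstraps controls from marker-positive, mutation-free
  cells, which fails if markers are globally silenced.
* The Cox stage estimates the hazard ratio of a *median split on a noisy
  score*; misclassification of samples near the median attenuates the
  estimate by a few percent relative to the planted value, visible in the
  recovery simulations.
* The differential-expression test is a two-group Wald test with
  moment-based dispersions; it is calibrated and powered in the tested
  regimes but is not a replacement for a full GLM framework when designs
  have covariates.

## Worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
run <- derive_ontogeny_signature(study$counts, study$mouse_table,
                                 study$homology, cnv = study$cnv,
                                 variants = study$variants,
                                 markers = study$markers, seed = 501)
run
head(run$signature)
run$gmm$overlap
```
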