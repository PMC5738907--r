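# tamont

Ontogeny deconvolution of tumor-associated macrophages (TAMs) from
single-cell and bulk transcriptomics.

Gliomas contain macrophages of two developmental origins — brain-resident
**microglia** and **blood-derived macrophages** (BMDM) that crossed the
blood–brain barrier — and the two are nearly impossible to separate with
classical surface markers in malignant tissue. `tamont` separates them
computationally:

1. **Cell annotation** — quality filtering (genes detected ≥ 800, reads
   ≥ 50 000, both configurable), CPM normalization, and classification of
   each cell as TAM / neoplastic / unassigned from marker expression,
   expressed somatic mutations (alt reads ≥ 2), and copy-number evidence
   (control-referenced per-segment z-scores with a direction-concordance
   rule).
2. **Signature derivation** — feature selection to murine-homologue
   candidates with mean CPM > 1, `log2(CPM/10 + 1)` transform,
   per-platform z-scoring, PCA with Kaiser-normalized Varimax rotation,
   a two-component Gaussian mixture partitioning the PC1 scores, and
   extraction of genes with |PC1 loading| > 0.2 (correlation-scale
   loadings). The lineage orientation of the axis is fixed by a Fisher
   exact test of loading sign against murine lineage.
3. **Validation** — multi-table factor analysis across capture platforms
   (first-singular-value scaling, partial-inertia ratio), an SC3-style
   consensus clustering (3 distances × 2 spectral transforms × k-means
   sweep → consensus matrix → hierarchical cut), and Matthews correlation
   between partitions.
4. **Propagation** — per-sample blood/microglia scores in bulk cohorts
   (means over signature genes, z-scored), Tukey's range test across
   glioma subtypes, median-split Cox proportional-hazards survival
   adjusted for age and gender (Efron ties), and per-structure enrichment
   in anatomically annotated regional atlases (one-vs-rest rank-sum, BH).

A first-class synthetic-data module (`sim_config()`, `simulate_study()`,
`simulate_single_cell_cohort()`, `simulate_bulk_cohort()`,
`simulate_regional_atlas()`) generates every input the pipeline consumes —
negative-binomial counts on two platforms with distinct depth/detection
profiles, planted lineage genes, neoplastic cells with clonal SNVs and
megabase-scale CNVs, survival cohorts with a planted hazard ratio, and
regional atlases with planted structure biases — together with full
ground-truth labels, so the whole pipeline is testable end to end without
any download.

## Worked example

```r
library(tamont)

study <- simulate_study(sim_config(seed = 1))        # all pipeline inputs + truth
run <- derive_ontogeny_signature(study$counts, study$mouse_table,
                                 study$homology, cnv = study$cnv,
                                 variants = study$variants,
                                 markers = study$markers, seed = 501)
run
#> <tam_signature_run> 237 candidates -> 66 signature genes (29 blood, 37 microglia); GMM overlap 0.0026
head(run$signature, 5)
#>      gene   lineage    loading
#> 1 HOM0174     blood -0.3077648
#> 2 HOM0015 microglia  0.3972749
#> 3 HOM0085 microglia  0.4235469
#> 4 HOM0069     blood -0.3383779
#> 5 HOM0163     blood -0.2948028
```

237 mouse-homologue candidates survive the expression filter; 66 genes
exceed the loading threshold and are labeled blood or microglia by the
sign of their loading on the oriented lineage axis (the sign itself is
arbitrary per run; the Fisher orientation step is what anchors it). The
mixture overlap 0.0026 says the two TAM populations on PC1 barely
intersect.

Cross-validation and survival propagation:

```r
cons <- consensus_cluster(run$expr_tam_z, run$candidates, k = 2, seed = 901)
matthews_correlation(run$partition$component, cons$label)
#> [1] 0.995

bc <- simulate_bulk_cohort(363, run$signature, true_hr = 3.44, seed = 77)
sc <- ontogeny_score(bc, run$signature)
cox_survival(bc, median_split(sc$blood_z))
#> <tam_cox> HR (high vs low) = 3.250 [2.441, 4.328], p = 7.23e-16
```

The consensus clustering agrees with the GMM partition at MCC 0.995, and
the median-split Cox model recovers a hazard ratio of 3.25 (95% CI
2.44–4.33) on a cohort simulated with a planted hazard ratio of 3.44 for
the high-blood-content half.

## Package layout

- `R/simulate.R` — synthetic-data generators and the study orchestrator
- `R/preprocess.R`, `R/pipeline.R` — QC, normalization, CNV scoring, cell
  classification, and the end-to-end derivation driver
- `R/signature.R` — transforms, Varimax PCA, 1-D GMM, signature
  extraction, enrichment, MFA, consensus clustering, MCC
- `R/de.R` — NB Wald differential expression, co-occurrence odds ratios,
  BH adjustment
- `R/cohort.R`, `R/regional.R` — bulk scoring, Tukey, median-split Cox,
  regional enrichment
- `R/io.R` — Matrix Market + TSV readers/writers
- `vignettes/ontogeny-deconvolution.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, numerical decisions,
  limitations
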