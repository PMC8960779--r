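# iccaSubtypes

Analytics for a two-subtype model of intrahepatic cholangiocarcinoma
(iCCA). The package re-implements, as a tested R pipeline, the bespoke
computations behind classifying iCCA into a perihilar large-duct-like
(S100P+SPP1−, "phl") and a peripheral small-duct-like (S100P−SPP1+, "pps")
subtype from single-cell and bulk transcriptomes:

* **Inferred-CNV malignant-cell calling** from scRNA-seq: per-gene
  reference centering, 100-gene sliding windows along each chromosome
  (CNVi), a per-cell CNV score (mean of squared CNVi), a Spearman CNV
  correlation against the tumor's top-3%-score cells, and the strict
  `score > 0.04 AND correlation > 0.5` malignancy rule.
* **Marker analytics**: positive-cell fractions, a mutual-exclusivity
  screen that nominates subtype markers (genes rarely expressed in
  seed-positive but extensively expressed in seed-negative malignant
  cells), four-way two-marker cell classes, and tumor-level subtype calls.
* **Bulk GMM subtyping**: per-marker two-component univariate Gaussian
  mixtures fitted by a hand-rolled, reproducible EM; posterior-0.5
  dichotomization; four-way sample classes and the cohort's concordant
  fraction.
* **Tumor heterogeneity**: cancer cell fractions from
  `VAF = CCF·p·m / (p·CNtot + 2(1−p))` with Clopper–Pearson intervals,
  CI-based clonality calls, genomic ITH (subclonal proportion), a
  transcriptomic ITH score (one minus correlation-to-centroid over top
  variable genes), and exact/approximate Wilcoxon rank-sum comparisons.
* **Signature scoring**: z-score-mean gene-set scores (macrophage
  pro-/anti-inflammatory and M1/M2 polarization lists ship as editable
  fixtures) with rank-sum subset comparisons.
* **A synthetic cohort generator** with known ground truth (CNV segments,
  mutually exclusive marker programs, bimodal bulk markers, clonal/subclonal
  mutation mixes), so every stage is testable without controlled-access
  data.

The intended users are computational biologists who want the subtype
assignment and heterogeneity statistics of this study design as auditable,
deterministic functions rather than a collection of one-off scripts.

## Worked example

```r
library(iccaSubtypes)

cohort <- generate_sc_cohort(sim_config(seed = 1))   # 2 tumors/subtype + 2 refs
cohort <- qc_filter(cohort)                          # <1000 UMIs / >20% mito
cnv <- infer_malignant_cells(cohort)
cnv
#> cnv_result: 1200 cells, 466 called malignant
#>   sample n_cells n_malignant frac_malignant called
#> 1    N01     200           0          0.000   TRUE
#> 2    N02     200           0          0.000   TRUE
#> 3    T01     200         118          0.590   TRUE
#> 4    T02     200         117          0.585   TRUE
#> 5    T03     200         116          0.580   TRUE
#> 6    T04     200         115          0.575   TRUE
```

The reference liver samples (N01/N02) yield no malignant calls; the four
tumors recover close to the planted 60% malignant fraction. The
exclusivity screen then nominates the second subtype's marker from the
seed marker alone:

```r
mal <- cnv$cells$cell_id[cnv$cells$malignant]
head(exclusivity_screen(cohort, cohort$marker_program$seed_marker, mal), 3)
#>     gene frac_pos_seedpos frac_pos_seedneg      delta candidate exclusivity_rank
#> 1 G02102       0.02283105        0.8704453 0.84761429      TRUE                1
#> 2 G01162       0.75342466        0.8461538 0.09272919     FALSE                2
#> 3 G00471       0.87671233        0.9554656 0.07875326     FALSE                3
```

The top-ranked gene (positive in 87% of seed-negative but 2% of
seed-positive malignant cells) is exactly the planted alternate marker.
Two-marker classification and tumor subtyping:

```r
mc <- classify_cells_two_markers(cohort, cohort$marker_program$seed_marker,
                                 cohort$marker_program$alt_marker, mal)
round(mc$global, 4)
#> G02101+G02102- G02101-G02102+ G02101-G02102- G02101+G02102+
#>         0.4592         0.4614         0.0687         0.0107
assign_tumor_subtype(mc)$subtype
#> [1] "G02101+G02102-" "G02101+G02102-" "G02101-G02102+" "G02101-G02102+"
```

About 92% of malignant cells fall in the two concordant classes; the
double-negative share (~7%) is what 5% dropout predicts, and all four
tumor labels match the planted subtypes. On the bulk side:

```r
bulk <- generate_bulk_cohort(108, subtype_mix = c(44, 44, 10, 10) / 108, seed = 1)
subtype_bulk_cohort(bulk$expr, seed = 1)
#> S100P+SPP1- S100P-SPP1+ S100P-SPP1- S100P+SPP1+
#>          43          45          10          10
#> concordant fraction: 81.48%
```

The whole analysis can also run as one orchestrated, seeded pipeline that
writes TSV/MTX/JSON artifacts and a hash-per-file `manifest.json`
(identical seed ⇒ identical hashes):

```r
run_pipeline(pipeline_config(seed = 1), out_dir = "icca_results")
```

or from a shell via the thin wrapper
`inst/scripts/icca-pipeline.R --out icca_results --seed 1`.

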