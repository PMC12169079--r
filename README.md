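# clonescape

Spatial tracking of hyperexpanded T cell clones in liver tissue.

Severe T-cell mediated liver injury — for example SARS-CoV-2
vaccine-associated liver injury (SVALI) — is driven by CD8 T cell clones
that expand massively, persist across biopsies, and concentrate at
specific tissue compartments. clonescape is an R package for the analysis
that characterises such clones across three modalities:

* **Bulk TCR-beta repertoire sequencing** of two longitudinal samples:
  clone frequencies `f_c = n_c / Σ n_k`, hyperexpansion calling
  (`f_c > 1%`, strict), clone sharing/persistence between samples, and
  CDR3 Levenshtein matching against an antigen-specificity reference.
* **Combined multiplex immunofluorescence + RNA in situ hybridisation
  (mIF/RISH)**: a five-zone liver decomposition — portal tract, 50 µm
  portal interface (PI) and lobular interface (LI) bands around the
  limiting plate (exact Euclidean distance transforms), and the
  intra-/extrasinusoidal lobule — with per-zone cell fractions, densities
  (cells/mm²), marker-positive fractions, a Fisher exact comparison of
  marker positivity between cell groups, and a permutation test for zonal
  enrichment.
* **Single-cell in situ transcriptomics (Xenium-style)**: transcript-to-cell
  aggregation, clone-positive CD8 calling (≥ 1 clone-probe transcript),
  signal bleed-through quantification, percent-expressing/dot-plot
  summaries, and Wilcoxon + Benjamini–Hochberg differential expression
  (significant iff log2FC > 0.25 and adjusted p < 0.05).

A synthetic-data generator (`generate_repertoire_pair()`,
`generate_tissue()`, `generate_cells()`, `generate_transcripts()`)
produces all inputs with a ground-truth manifest, so the whole pipeline is
exercisable and testable without patient data. The
`vignettes/clone-tracking-methods.Rmd` vignette documents the models,
parameters and design choices.

## Worked example: clone tracking between a biopsy and an explant

`svali_repertoire_params()` encodes a published repertoire structure (189
biopsy clones, 508 explant clones, 59 shared, 12/9 hyperexpanded, top
clones at 16%/14.5%) as generator conditions:

```r
library(clonescape)

pair    <- generate_repertoire_pair(svali_repertoire_params(seed = 42))
biopsy  <- call_hyperexpanded(compute_frequencies(pair$sample_a))
explant <- call_hyperexpanded(compute_frequencies(pair$sample_b))

head(explant[, c("clone_key", "count", "frequency", "rank", "hyperexpanded")], 3)
#>                clone_key  count frequency rank hyperexpanded
#> 1 TRBV7-9|CASSVDRGSYEQYF 144768  0.144768    1          TRUE
#> 2      TRBV2|CASSPDIEAFF  53398  0.053398    2          TRUE
#> 3 TRBV20-1|CASSLEGYTEAFF  52068  0.052068    3          TRUE

compare_samples(biopsy, explant)
#> Clone sharing: biopsy vs explant
#>   shared 59 | unique 130 / 449
#>
#>    hyper_in_both  hyper_in_a_only  hyper_in_b_only hyper_in_neither
#>                3                7                0               49

match_cdr3(explant[explant$hyperexpanded, ], spike_reference(),
           max_edit_distance = 0)[, c("clone_key", "epitope", "edit_distance")]
#>                clone_key   epitope edit_distance
#> 1 TRBV7-9|CASSVDRGSYEQYF YLQPRTFLL             0
#> 2      TRBV2|CASSPDIEAFF YLQPRTFLL             0
#> 3 TRBV20-1|CASSLEGYTEAFF YLQPRTFLL             0
```

The top explant clone holds 14.5% of all reads; 59 clones are shared with
the biopsy, three of them hyperexpanded in both samples, and exactly those
three match the (synthetic) spike-specific CDR3 reference at edit distance
0 — the planted ground truth. The spatial stages follow the same pattern:
`build_zone_map()` on binary masks, `assign_zones()` +
`zone_statistics()` + `zone_enrichment_test()` on a cell table, and
`aggregate_transcripts()` + `call_tcr_positive()` +
`differential_expression()` on a transcript table; `run_pipeline()` ties
them together from a single `pipeline_config()`.

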