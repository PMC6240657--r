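# nsafpipe

Label-free quantitative proteomics from protein-level spectral counts,
for experiments with a treatment × replicate design — the motivating
case is a tomato developing-pollen study with four treatments (control,
heat stress, and each preceded by an ethylene-releaser spray) and three
biological replicates. The package takes a proteins × samples table of
PSM (peptide-spectrum match) counts plus protein lengths and a sample
design, and carries it through quantification, filtering, differential
expression, multivariate structure and functional enrichment — with a
ground-truthed simulator so every stage is testable without any
instrument data.

## The model

Abundance is quantified by the normalized spectral abundance factor:

```
NSAF_k = (PSM_k / L_k) / Σ_i (PSM_i / L_i)
```

with `L` the protein length; values sum to 1 per sample. A protein
enters the dataset only if detected in **all** replicates of at least
one treatment (`presence_filter()`), and is called differentially
expressed between two treatments iff (1) it is fully detected in one of
them, (2) a two-sided t-test on per-replicate NSAF gives p ≤ 0.05 *or*
the protein is absent from every replicate of one treatment, and (3)
the signed fold change of treatment means is at least 1.5 in magnitude
(`de_call()`). Fold changes are signed with magnitude ≥ 1 (a drop from
1.2 to 0.1 reports −12, not 0.083); presence/absence cases carry an
`Inf`/`-Inf` sentinel and an explicit reason. Around this rule the
package provides PCA with loading-sum summaries (`pca_fit()`,
`loading_sum_profile()`), k-means clustering of proportion-normalized
treatment profiles (`profile_normalize()`, `kmeans_fit()`),
MapMan-style bin categorization (`categorize()`), hypergeometric GO
enrichment with BH-FDR (`go_enrich()`), Venn partitions (`venn()`,
`unique_terms()`) and a one-command orchestration (`run_pipeline()`).

## Worked example

```r
library(nsafpipe)

fx  <- pollen_fixture(seed = 2026)     # synthetic 4x3 pollen-style dataset
x   <- nsaf(fx$counts)                 # NSAF, reporting scale x1000
ret <- presence_filter(fx$counts)$retained
length(ret)
#> [1] 797                              # of 1000 simulated proteins

res <- de_call(x, "P-C", "P-HS", retained = ret)
s <- updown_summary(res)
sprintf("%d DE proteins: %d up (%d%%), %d down (%d%%)",
        s$n_total, s$n_up, s$pct_up, s$n_down, s$pct_down)
#> [1] "155 DE proteins: 41 up (26%), 114 down (74%)"

signed_fold(1.2, 0.1)                  # control 1.2 -> heat stress 0.1
#> [1] -12

pca <- pca_fit(x, ret)
round(tapply(pca$scores[, 1], fx$counts$design$treatment, mean), 1)
#>    P-C  P-E-C P-E-HS   P-HS
#>  -17.8  -16.2    3.8   30.2          # heat stress is the PC1-extreme group

e <- go_enrich(res$accession[res$call & res$fold < 0], ret, fx$annotations)
head(as.data.frame(e)[, c("term", "n_fg", "n_bg", "p_value", "q_value")], 2)
#>         term n_fg n_bg      p_value      q_value
#> 1 GO:0006412   71   94 1.260003e-50 1.386003e-49   # translation, depleted
#> 2 GO:0006099   31   46 1.262554e-17 6.944046e-17   # TCA cycle, depleted
```

The fixture was designed with exactly this structure: heat stress
suppresses the translation and TCA bins and induces a small stress bin,
and the ethephon-pretreated heat-stress proteome sits between stress
and control — which is what the PC1 centroids and the enrichment tables
above recover.

`run_pipeline(counts, annotations, pipeline_config(seed = 1), outdir = "out/")`
executes every stage and writes deterministic TSV tables. A thin CLI
over the same functions is at `inst/scripts/nsafpipe.R`
(`simulate`, `quantify`, `filter`, `de`, `pca`, `cluster`, `enrich`,
`venn`, `run`).

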