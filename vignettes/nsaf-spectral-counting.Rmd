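---
title: "Spectral-count proteomics with NSAF: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count proteomics with NSAF: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsafpipe)
```

# The problem

Label-free shotgun proteomics assigns MS/MS spectra to peptides and
peptides to proteins; the number of peptide-spectrum matches (PSMs)
accumulated by a protein in a run is a crude but robust proxy for its
abundance. `nsafpipe` analyses protein-level PSM count tables from
designed experiments — the motivating design is a plant-stress study
with four treatments (control, heat stress, and each with an
ethylene-releaser pre-treatment) and three biological replicates — and
answers the questions such studies ask: which proteins changed, which
functional processes they belong to, and how the treatment proteomes
relate to one another as wholes.

# Quantification: NSAF

Spectral counts confound abundance with protein length (a long protein
offers more tryptic peptides) and with per-run depth. The normalized
spectral abundance factor corrects both:

$$\mathrm{NSAF}_k = \frac{\mathrm{PSM}_k / L_k}{\sum_{i=1}^{N} \mathrm{PSM}_i / L_i}$$

where $L_k$ is the protein length in amino acids and the sum runs over
all $N$ proteins in the sample. Raw NSAF values sum to 1 within each
sample; they are relative abundances, and the whole downstream analysis
is compositional in that sense. `nsaf()` stores values multiplied by a
reporting `scale_factor` (default 1000), which places typical values for
a ~1,000-protein experiment in the convenient 0.1–10 range; the
magnitude of published NSAF-derived tables in this field is consistent
with such a scale, but the raw sum-to-one contract always holds for
`values / scale_factor`, and the scale cancels out of every test and
fold change downstream.

Zeros are meaningful and are never imputed at quantification time: a
protein with no spectra has NSAF exactly 0. Pseudocounts would blur the
presence/absence distinction that the differential rule below depends
on.

# The replicate-presence filter

A single PSM in a single run is weak evidence that a protein is really
there. The dataset filter retains a protein only if it was detected
(PSM > 0) in *every* replicate of at least one treatment
(`presence_filter()`, mode `"all"`; an integer mode generalises the
threshold). This deliberately keeps proteins that are entirely absent
from some *other* treatment — absence from all replicates of one
condition, combined with consistent detection in another, is itself the
strongest kind of differential signal spectral counting can produce.

# The three-condition differential-expression rule

`de_call()` declares a protein differentially expressed between a
reference treatment and a treatment of interest iff:

1. it was detected in all replicates of at least one of the two
   treatments;
2. a two-sided two-sample t-test on the per-replicate NSAF values gives
   p ≤ 0.05, **or** the protein was detected in no replicate of one of
   the treatments (in which case no test statistic exists and the
   presence/absence pattern substitutes for it);
3. the fold change between the treatment-mean NSAF values is at least
   1.5.

Fold changes are reported signed with magnitude ≥ 1: an increase is
$+\bar{b}/\bar{a}$, a decrease $-\bar{a}/\bar{b}$, and a
presence/absence case is serialized as `Inf`/`-Inf` with a companion
`reason` column (`absence`), keeping tables numeric-sortable while
unambiguous. Means include zeros; fold changes are ratios of arithmetic
treatment means, the plain reading of "fold change in NSAF values"
(replicate-wise ratio alternatives would be undefined at zeros).

Design choices worth stating:

* **Test variant.** The default is Student's equal-variance t-test; at
  n = 3 per group the classical test is the conventional choice and the
  pooled variance estimate is less unstable than Welch's. Welch is
  available via `de_config(test = "welch")`.
* **Degenerate variances.** When both groups have zero variance the t
  statistic is undefined; the limit is taken: p = 1 for equal means,
  p = 0 for a deterministic difference.
* **No multiple-testing correction in the call.** The rule uses raw
  p ≤ α, mirroring common practice for this rule; a Benjamini–Hochberg
  `q_value` column is emitted for transparency but never used in the
  call.
* **The DE universe** is the presence-filtered set over the whole
  design (plus anything fully detected in one of the two compared
  treatments), not recomputed per pair, so all comparisons share one
  dataset.

## Calibration of the rule

The t-test branch is conservative by composition: the fold filter can
only remove calls, so under a true null its call rate is below α. The
absence branch is different in kind: it is not a test with a
significance level but a deterministic reading of the detection
pattern. Under very sparse spectral budgets (a few PSMs per protein),
multinomial sampling alone occasionally produces all-replicate zeros,
and the rule then calls such a protein — by design. In our simulations
at a mean depth of ~10 PSM/protein the full rule's null call rate sits
at ≈ 0.05 (t-test branch ≈ 0.04, the remainder absence calls); at
depths where every protein is reliably detected, absences cannot occur
and the rate drops well below α (≈ 0.02, the fold filter biting
harder as folds concentrate near 1). Users working at shallow depth
should read `reason == "absence"` calls as detection statements, not
p-values.

# Multivariate structure

`pca_fit()` runs PCA with samples as observations and retained proteins
as variables, mean-centered and unscaled by default. Centering-only is
the common choice for NSAF abundances — unit-variance scaling would let
the many near-zero proteins dominate; both scaling and a log transform
(with an offset, since zeros are exact) are exposed as flags because
reasonable analysts differ here. Component signs are canonicalized
(largest-magnitude loading positive) so results are deterministic.
`loading_sum_profile()` summarises what a component *means*: the summed
treatment-mean NSAF of the n most positive (or most negative) loadings,
plotted per treatment, shows which condition gained or lost that end of
the axis.

For clustering, each protein's per-treatment mean profile is first
rescaled to sum to 1 (`profile_normalize()`), so clusters group
proteins by the *shape* of their response, not their absolute
abundance. `kmeans_fit()` is Euclidean k-means (k = 30 by default, a
conventional granularity for surveying several hundred profiles) with
k-means++ initialisation, a required seed, and best-of-50 restarts;
profiles are sorted by accession before seeding so assignments are
invariant to input order. The iterations themselves are delegated to
`stats::kmeans()`; an initialisation that collapses to an empty cluster
is re-seeded from the farthest point and the restart retried.

# Categorization, enrichment and set comparisons

`categorize()` assigns each protein the first dot-component of its
MapMan-style bin path (unannotated proteins fall into
`"not assigned.unknown"`). `go_enrich()` tests each directly annotated
GO term for over-representation with the upper-tail hypergeometric
probability and controls the FDR across terms with Benjamini–Hochberg
(threshold 0.05 by default). No GO-graph ancestor propagation is
performed: only terms actually attached to proteins in the annotation
file are tested, which keeps the test honest when the ontology file is
not available. The background defaults to the set the user supplies;
enriching against the full annotated genome or against the detected
dataset are both legitimate and give different questions' answers, so
the choice is explicit in the API.

`venn()` computes all exclusive intersection regions of 2–4 sets
exactly (more with `allow_many = TRUE`), with integer percentages of
the union; `unique_terms()` reports the terms enriched in exactly one
of several comparisons. Percentages throughout the package are rounded
half-away-from-zero (`percent_int()`), the convention of printed
summaries such as "38 (29%)".

# The synthetic-data generator

`simulate_counts()` generates datasets with the statistical structure
the analysis assumes, plus ground truth for recovery tests:

* lengths log-uniform on 100–3,000 aa;
* baseline relative abundances log-normal (sdlog 1.2 by default, a
  dynamic range of roughly three orders of magnitude);
* treatment effects as per-protein fold factors (by default 10% of
  proteins get a 4-fold shift in one random non-reference treatment;
  an explicit effect matrix supports bin-structured designs);
* per-sample sampling weights proportional to abundance × length ×
  log-normal replicate jitter (sdlog 0.2) — length enters the weight
  precisely so that NSAF's length division has something real to undo;
* abundance-dependent detection dropout: a logistic in the expected
  per-sample PSM count (midpoint 1 PSM, width 0.5), which produces the
  all-replicate absences the DE rule's absence branch needs;
* counts multinomial over the detected proteins with a fixed spectral
  budget (20,000 PSM/sample by default), so per-sample totals are exact
  and the compositional character of NSAF is part of the simulation.

`pollen_fixture()` freezes one such dataset shaped like the motivating
study: 1,000 proteins, the four treatments above, heat stress pushing
the translation (`protein.synthesis`) and `TCA` bins down 4-fold and a
small `stress` bin up 4-fold, the ethephon + heat-stress treatment
attenuating every shift to 2-fold, and ethephon alone neutral; ~72% of
proteins carry bins, and each themed bin carries a toy GO term so the
designed effects are recoverable by enrichment.

What the generator does *not* emulate: peptide-level effects (shared
peptides, digestion variability), intensity information,
missing-not-at-random mechanisms beyond the logistic dropout, and
correlated replicate structure. Passing tests on synthetic data
therefore demonstrate the pipeline's internal correctness and its
behavior under the stated noise model — not performance on any real
instrument's output.

## Problem sizes used in the checks

The shipped test-suite simulations use sizes chosen to make the checked
properties statistically meaningful on a single CPU: the null
calibration of the DE rule uses 2,000 proteins × 200 draws at a
200,000-PSM budget (deep enough that no protein is ever absent, so the
rate bound isolates the testing branch); the recovery check uses five
datasets of 500 proteins at the default 20,000-PSM budget with
baseline sdlog 0.8 — a "moderate counts" regime, mean ≈ 40
PSM/protein. The moderate-counts choice is a power statement, not a
convenience: with three replicates, an equal-variance t-test on NSAF
values detects a 4-fold shift reliably only when counting noise
(CV ≈ $1/\sqrt{E}$ at expected count $E$) is at or below the biological
replicate noise (CV ≈ 0.2), i.e. $E \gtrsim 15$–25. Under the
fixture's wider, more realistic abundance spread (sdlog 1.2 with
dropout), roughly a third of the designed effects sit below ~2 expected
PSM — beneath the detection floor of a 20,000-spectra experiment —
so absolute recall there is bounded by detectability (≈ 0.6 at
default settings), while recall among presence-qualified proteins and
the sign concordance of recovered folds remain high. That gap is a
property of spectral counting at finite depth, not of the rule.

# Known limitations

* NSAF is compositional: a large change in an abundant protein shifts
  every other protein's NSAF slightly in the opposite direction. The
  simulator's ground-truth folds include this closure effect; real
  interpretation should too.
* The t-test on n = 3 NSAF values is a blunt instrument; moderated
  tests would gain power but are deliberately out of scope because the
  pipeline reproduces a specific published rule.
* Enrichment without ancestor propagation understates broad GO
  categories when annotation files carry only leaf terms.
* k = 30 is a survey granularity, not an estimate of the number of
  true profiles; no attempt is made to select k.
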