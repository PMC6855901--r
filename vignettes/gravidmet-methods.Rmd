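---
title: "Methods: the gravidmet early-pregnancy metabolome pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gravidmet early-pregnancy metabolome pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravidmet)
```

`gravidmet` analyses untargeted plasma metabolomics comparisons of pregnant
(8–16 weeks of gestation) and non-pregnant women. This vignette documents
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-cohort generator does and does not emulate, the
numerical conventions, and the limitations a user should know about.

## The data model

The pipeline's central object is an `abund`: a metabolites × samples matrix
of total ion counts (TIC, arbitrary units — the abundance surrogate of
untargeted LC/MS platforms) plus a same-shape logical *detection mask*.
Missing measurements are left-censored observations, not missing-at-random:
a blank cell means "below the limit of detection". They are therefore kept
as `NA` with `detected = FALSE` — never encoded as 0, since 0 is a legal ion
count after scaling — until imputation fills them in, and imputation never
flips a detection flag, so downstream steps (QC, decay fitting) can always
distinguish measured from imputed values.

A stage tag (`raw → scaled → imputed → decay_corrected → adjusted`) enforces
the preprocessing order at run time; calling a stage out of order errors
rather than silently producing a differently normalized matrix.

Gestational age uses the clinical weeks+days notation (`"12w4d"` = 12 + 4/7
weeks); parsing and formatting are exact inverses at day resolution.
Sample order everywhere is the metadata row order, so all outputs are
deterministic functions of the input files.

## Preprocessing

**Run-day scaling.** Instrument batches ("run days") shift TIC values
multiplicatively. For each metabolite, each day's values are multiplied by
`(grand median of detected values) / (day median of detected values)`.
The method's defining requirement is only that per-day medians agree; the
anchor at the pooled median is this package's choice because it preserves
the overall scale of each metabolite. Factors use detected values only; a
day with no detected values gets factor 1. The operation is exactly
idempotent: once all day medians equal the grand median, the grand median of
the scaled data is unchanged, so a second pass computes unit factors.

**Detection filter.** Metabolites detected in fewer than
`detection_min_samples` (default 10 — half the smaller group of the
50 + 21 design) are dropped. The boundary is inclusive: detected in exactly
10 samples is kept.

**LOD imputation.** Censored cells become `imputation_fraction` (default
0.99) × the metabolite's minimum detected value, computed *after* scaling so
the minimum is on the common scale. This deliberately produces within-sample
ties at the bottom of each metabolite's distribution; the rank tests
downstream use tie corrections for exactly this reason.

**Storage-decay correction.** Long-frozen samples lose some compounds.
Using a reference sample set with known storage times, each metabolite is
screened with a two-sided Spearman test of abundance vs storage time at an
*unadjusted* α = 0.05 — this is a per-metabolite screening decision, not an
inference, so no FDR correction is applied. Screened-in metabolites get an
ordinary least-squares slope of natural-log abundance on storage time
(consistent with exponential decay `A0·e^(−kt)`), fitted on detected values
only — imputed constants would flatten the slope. Study values are then
back-corrected by `exp(−slope · storage_time)` to storage time zero. With no
reference samples the stage is skipped with a warning: deposited data sets
are typically already decay-corrected.

**Quantile normalization.** The "adjusted abundance" branch maps every
sample onto the per-rank mean of the samples' sorted value vectors, the
microarray-era procedure. Tied values receive the mean of the reference
values across their tied ranks. Two properties are worth stating precisely:
with no within-sample ties, all samples share the reference vector exactly;
and the transform is idempotent. It is *not* invariant to rescaling a single
sample — the reference is recomputed from all samples, so changing one
sample perturbs every output slightly. Each sample's ranks, however, fully
determine where it lands on the reference.

**Intra-assay QC.** For technical replicates of one sample, a per-metabolite
CV(%) = 100·sd/mean (sample standard deviation, n − 1) over the detected
replicate values, restricted to metabolites detected in at least
`ceiling(0.8·r)` of r replicates (4 of 5 in the canonical design); the
median CV is the platform's headline precision figure. Instrument and
process RSD from spike-in standards are not modelled (proprietary
chromatograms); those report fields stay `NA` unless such samples are
supplied.

## Differential abundance

Each metabolite is tested with a two-sided Mann-Whitney-Wilcoxon U test
between pregnant and non-pregnant samples. The exact null distribution is
enumerated only for tie-free groups with both sizes ≤ 8; everything else —
in particular the 50 vs 21 design, which always has imputation ties — takes
the tie-corrected normal approximation with a 0.5 continuity correction.
Fixing this switch makes results reproducible and documented rather than
dependent on a library's internal size heuristics.

FDR control is Benjamini-Hochberg step-up. The significance call is the dual
criterion: `q < 0.1` **and** `max(FC, 1/FC) > 1.5`, where FC is the ratio of
group medians (pregnant / non-pregnant, so FC < 1 means lower in pregnancy).
The magnitude cut-off is symmetric in direction, treating a 30-fold increase
and a 100-fold decrease under one rule. Fold changes are computed on the
same matrix being tested, so the unadjusted and adjusted branches each get
their own fold changes.

The direction split among significant metabolites is tested with an exact
two-sided binomial test at null proportion 0.5. For splits like 229 of 281
the p-value is ~1e-27; `binom.test`'s summation handles this, and the test
suite verifies it against an exact rational-arithmetic tail summation.
Two-sided was chosen over one-sided (the convention is ambiguous in this
literature); the package reports the exact count and p-value rather than a
rounded percentage.

The power statement uses the normal approximation for a two-sided two-sample
comparison, `Φ(d/√(1/n₁+1/n₂) − z_{1−α/2})` plus the minor tail, so d = 0
returns exactly α. At the design sizes (50, 21) and d = 0.75 this gives
0.822.

## Pathway over-representation

Per sub-pathway, a 2×2 table {in-pathway, out-of-pathway} ×
{significant, not} over the *detected* metabolite universe (all metabolites
that entered testing, not all annotated metabolites), tested two-sided with
Fisher's exact test and BH-adjusted across pathways. Two-sided matches the
default of the analysis environments this field uses; a one-sided
enrichment-only test would differ for depleted pathways. Metabolites with
sub-pathway `"unannotated"` stay in the background totals but get no row.
Enrichment defaults to the unadjusted-branch significant set.

## Networks, clusters, trends, sensitivity

Spearman correlations among metabolites are computed over pregnant samples
on adjusted abundances; p-values use the t approximation
`t = ρ√((n−2)/(1−ρ²))`. Edges connect pairs with |ρ| above `edge_abs_rho`
(default 0.5); node degree and its mean/IQR summarize each enriched
pathway's connectivity. Clustering is agglomerative with average linkage on
`d = 1 − ρ` — not `1 − |ρ|`, so anti-correlated metabolites are kept apart,
matching the interpretation of clusters as biologically co-regulated groups
(an `absolute = TRUE` flag provides the variant) — with the dendrogram cut
into exactly `n_clusters` (default 25) clusters. Linkage is a documented
package choice; the literature this follows does not state one.
"Significantly correlated pairs" are defined as BH FDR < 0.1 across all
pairwise two-sided p-values, sorted by |ρ|.

Gestational-age association is Spearman (rank-based, like all covariate
associations here) of adjusted abundance vs gestational age among pregnant
samples, over the candidates significant in the *adjusted* differential
analysis, with BH control across candidates. The OLS log2-abundance slope is
attached for plotting only. Sensitivity re-analyses rerun the unadjusted
differential analysis after excluding (a) the five oldest white non-pregnant
participants (age ties broken by metadata order, deterministically) or (b)
all self-reported smokers, and report the Spearman concordance of
fold-change vectors over all metabolites plus the list of metabolites whose
significance flag flips. Concordance is defined over all metabolites, not
only significant ones.

PCA for visualization runs on log2 abundances with per-metabolite centering
and unit-variance scaling; zero-variance metabolites are dropped with a
warning; component signs follow the convention that the largest-magnitude
loading is positive, so scores are reproducible across sample orderings.

## The synthetic-cohort generator

`simulate_cohort()` draws, in order: per-metabolite log2 baselines
μ ~ U(10, 20) and dispersions σ ~ U(0.3, 1.2); one latent factor per
sub-pathway with loading chosen so within-block Spearman correlation ≈
`block_rho` (via the Gaussian-copula relation ρ_Pearson = 2·sin(π·ρ_S/6));
a group effect on a 44% subset, negative (lower in pregnancy) with
probability 0.81 and log2 magnitude ~ U(log2 1.5, 5); gestational-age slopes
on 14 differential metabolites (±U(0.05, 0.15) log2/week over GA ~ U(8, 16)
weeks); per-(metabolite, run-day) batch shifts ~ N(0, 0.3 log2) over 4 run
days; exponential storage decay on a 15% subset at k ~ U(0.02, 0.08)/month
with storage times ~ U(0, 36) months on study and reference samples; five
technical replicates of the first pregnant sample with multiplicative
log-normal noise at CV 12%; left-censoring at each metabolite's pooled 10%
quantile; and demographics matching the study's marginals (ethnicity, age,
smoking per group). One seeded generator drives every draw, so a seed
reproduces the cohort bit-exactly, and the planted truth (differential set,
log2 fold changes, GA slopes, decay rates, LOD thresholds, batch shifts) is
returned for recovery tests.

Where the design left values open, they were fixed once at what is realistic
for this platform class: 4 run days with 0.3 log2 batch SD (batch effects
visible but smaller than biology), 30 sub-pathways under 8 super-pathways
(median pathway size ~20, like commercial annotation tables), decay rates
0.02–0.08/month (0.5–3 natural-log units over a 36-month archive), 20
reference samples, and GA slopes of 0.05–0.15 log2/week (0.4–1.2 log2 across
the 8-week window — detectable but not dominant).

What the generator does *not* emulate: pathway-level concentration of the
differential signal (differential status is independent of pathway
membership, so over-representation is null at the defaults — enrichment
power is exercised in the test suite with explicitly planted blocks);
heavy-tailed or multimodal abundance distributions; missingness mechanisms
other than hard left-censoring; drift within a run day; and any
metabolite-identity-level biology. Passing recovery tests therefore shows
the pipeline recovers effects under a log-normal, block-correlated,
left-censored model — not that it is robust to everything real data can do.

## Numerical conventions and edge cases

- Imputation requires scaling first; quantile normalization requires a fully
  imputed matrix; violations error with the expected stage named.
- A metabolite with no detected values cannot be imputed and errors
  (the detection filter removes such rows first).
- Constant metabolites get `NA` Spearman correlations, are excluded from
  edges and FDR control, and become singleton clusters beyond `k`.
- Abundance CSVs serialize doubles at 17 significant digits, so a
  write/read round trip is bit-exact, and the committed fixture regenerates
  byte-identically from its seed.
- All statistical tests are deterministic; the only randomness in the
  package is the seeded generator.

## Known limitations

**Quantile normalization under asymmetric change.** With 44% of metabolites
changed and 81% of those decreased, pregnant samples' whole distributions
sit lower, and quantile normalization — which assumes distributional
equality is nuisance — compensates by shifting pregnant samples up. On the
synthetic cohorts this inflates the adjusted-branch significant count above
the unadjusted one and dilutes the gestational-age candidate set. This is a
property of the method under strongly asymmetric signal, and it is why the
headline criterion is applied to the unadjusted branch while the adjusted
branch is reported alongside.

**Median-based fold changes near the LOD.** For metabolites censored in most
of one group, the group median sits at the imputed constant, so fold changes
saturate at the censoring boundary (values like "<0.01" in the field's
tables); recovery of the planted log2 FC is correspondingly bounded for the
most extreme effects.

**Covariates.** Confounding is handled by subgroup exclusion (the
sensitivity rules), not by regression adjustment; that mirrors the analysis
this package implements and is a deliberate non-goal.

## Problem sizes used by the tests

Unit and property tests run on small matrices (tens of metabolites, tens of
samples). End-to-end recovery checks use the design sizes — 637 metabolites,
50 + 21 samples — over 20 seeds (effect recovery), 50 seeds (null false
discovery proportion), and 250-metabolite cohorts over 12 seeds for decay
recovery; the package treats these as the canonical validation conditions,
and `scripts/acceptance.R` re-runs the same measurements from scratch.
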