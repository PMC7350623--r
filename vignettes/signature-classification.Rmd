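---
title: "Methods: signature-based diagnosis of rare pediatric CNS tumor entities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based diagnosis of rare pediatric CNS tumor entities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnssig)
```

## The problem

Four molecularly defined pediatric brain tumor entities — CNS NB-FOXR2,
CNS EFT-CIC, CNS HGNET-MN1 and CNS HGNET-BCOR — were carved out of the
retired CNS-PNET category by DNA methylation profiling. They are rare,
morphologically mimic other high-grade tumors, and their recognition
changes clinical management. Methylation profiling is not available in
every center, but each entity carries a characteristic gene-expression
signature, and probe-counting platforms (NanoString nCounter) measure such
signatures robustly in degraded FFPE RNA. `cnssig` models that diagnostic
route end to end: discovering compact marker panels from expression arrays,
counting them in tumor cohorts, and calling entities by clustering against
reference samples with prior methylation diagnoses.

Real patient data is not distributable, so the package pairs every analysis
stage with a seeded generator that plants known signatures; the tests and
the acceptance script measure how faithfully each stage recovers the
planted truth.

## Generative models

**Discovery stage.** Probe intensities are log-normal:
`log2 x ~ N(baseline + effect, sd)`, with `effect > 0` only for a planted
marker probe in its own class. Defaults: baseline 6 log2 units (modest
expression on a typical array scale) and sd 1 — comfortably above the
`sqrt(0.25)` variance-filter floor, so null probes survive filtering and
p-values stay uniform under the null. Linear-scale intensities (`2^log2x`)
are reported, because the discovery chain itself performs the log2
transform.

**Detection stage.** Counts are negative binomial with per-probe mean and
shared dispersion (`variance = mu + phi * mu^2`, default `phi = 0.05` —
mid-range for probe-count data). Every lane is multiplied by a log-normal
efficiency factor (sdlog 0.15), the only FFPE-degradation effect modeled;
technical normalization must remove it. Background marker means are 20
counts (near-noise), housekeeping genes sit at 2000/1000/500 counts,
positive controls form a fixed factor-4 design ladder (16384 down to 16)
scaled by lane efficiency, and negative controls average 2 counts. Samples
of glioma-like background diagnoses (HGG, GBM) additionally express the
glioma panel (default 3-fold); planted entity samples can be flagged to
express it too, which is how dual-signature tumors are emulated.

**Planted-fold calibration.** Hybridization QC measures, for a marker
probe, the fold of the reference sample over the *mean of all remaining
samples* — including the entity's other positive samples. With `m`
equally-elevated positives among `N` samples that fold is bounded by
`(N-1)/(m-1)` no matter how strong the elevation, so a drawn target fold is
clamped to 80% of that bound and the shared per-probe elevation is then
solved exactly from the clamped target. Clamped targets remain inside the
configured 3.9–92.7× range. The alternative — boosting only the reference —
would reproduce arbitrarily large folds but make the reference atypical of
its own entity, undermining the reference co-clustering that the calling
rule anchors on; references are deliberately ordinary planted samples,
merely tagged.

The default cohort compositions mirror the study setting: 92 supratentorial
samples (80 background: 25 HGG, 17 PNET, 18 EPN, 9 CPC, 7 ATRT, 2 ETMR,
2 NOS; planted: 1 EFT-CIC, 3 NB-FOXR2, 4 HGNET-MN1, 4 HGNET-BCOR, with one
reference per entity and two for NB-FOXR2) and 95 infratentorial samples
(93 background; 2 HGNET-BCOR, one of them the reference) — 187 in total.
Sample counts are configuration, not constants, because the source material
leaves the exact sample-versus-patient bookkeeping ambiguous (e.g. a
relapsed HGNET-BCOR sample).

## Marker discovery

Quantile normalization (per compartment), log2, variance filter at 0.25
(strict `<` removal: a probe at exactly 0.25 is retained). The resampled
statistic compares the target class `n` times against equally sized
subsamples of the pool, without replacement per repetition; when the pool
is smaller than the target the whole pool is reused with a warning. The
*t*-test is two-sided pooled-variance Student (Welch behind a flag). Fold
change is the difference of log2 means, reported also as `2^diff`;
averaging on the log scale matches the log2-transformed data and is
symmetric under label exchange. Ranking is mean p ascending, ties broken by
mean log2 fold descending, then probe id — fully deterministic. Selection
truncates to the top 100 by significance *first* and then applies the
10-fold filter, reading "the top significant genes which were up-regulated
at least 10 fold" in that order.

Degenerate repetitions (zero within-group variance on both sides) define
p = 0 when the means differ and p = 1 when they are equal, preventing NaN
propagation from constant probes.

A practical caveat the tests account for: quantile normalization forces all
samples onto a common distribution, so a class-specific planted tail is
compressed toward the cohort tail — at the study's class fractions the
realized mean log2 fold sits 1–1.5 below the planted effect. Recovery
tests therefore plant effects of 5–6.5 log2 (folds 32–90, mid-range of the
published marker folds) so the post-normalization fold clears the 10-fold
cut by a sampling-noise margin rather than straddling it.

## Normalization and hybridization QC

Both normalization stages rescale each lane by `anchor / geomean(control
probes)`. The biological stage anchors on the cohort mean of housekeeping
geomeans. For the technical stage the package's default anchor is the
geometric mean of the CodeSet's positive-control *design* levels — a
constant of the assay, not of the cohort. This choice is deliberate: with a
constant technical anchor the two-factor composition cancels any per-lane
scale factor *exactly* (rescaling every count of a lane by `k > 0` leaves
its normalized endogenous values unchanged to floating-point precision),
whereas a cohort-mean anchor leaks a term `(k-1)*g_i/(n*M)` through the
cohort average and the cancellation is only approximate. The cohort-mean
anchor remains available (`anchor = "cohort_mean"`) and is the behavior a
lone lane or an anchor-free run would use. Lanes with a zero
positive-control count are flagged and left unscaled; a zero housekeeping
count drops that gene from the lane's geomean and flags the lane.
Negative-control background subtraction (mean + 2 sd per lane, floored at
zero) exists behind a flag and is off by default.

Hybridization QC is computed on post-normalization linear counts ("fold"
language implies linear ratios): `fold = reference / mean(others)`, pass
iff fold > 1, indeterminate (not pass) when the remaining samples average
zero.

## Classification

Clustering is agglomerative average linkage (UPGMA) on Euclidean distances
of log2 marker values, restricted to the compartment's entity panels plus
the glioma panel; supratentorial and infratentorial cohorts are always
clustered separately, and entities are only callable in compartments where
their panel exists (NB-FOXR2 and EFT-CIC are supratentorial-only).

The published assignment was visual co-clustering with reference samples;
the package fixes an explicit, testable rule. A sample is called entity `g`
iff:

1. its signature z-score for `g` (panel-mean log2 expression, standardized
   across the cohort) is at least τ = 2;
2. its *absolute* elevation — panel-mean score minus the cohort median
   score — is at least 1 log2 (a 2-fold mean elevation);
3. `g` is the arg-max among passing entities (an exact tie yields no call
   and an ambiguity flag);
4. when `g` has a reference in the cohort, the sample shares a cluster with
   that reference when the tree is cut into
   `k = (#entities with references) + 1` clusters.

Condition 2 is load-bearing. Cohort z-scores are relative: in a cohort with
*no* expressing sample the standardized noise still crosses any fixed τ
somewhere, so a z-only rule necessarily produces false calls on
signature-free cohorts; and in a cohort where positives are a fraction `p`
of samples the positive-class z is bounded by `sqrt((1-p)/p)` regardless of
effect size. The absolute floor costs nothing against genuine signatures
(planted markers sit ≥ log2(3.9) ≈ 2 above background) and eliminates both
failure modes. For the same reason the glioma-contrast analysis — where
glioma-high samples are the *majority* (21 of 28 in the modeled
re-analysis, bounding their z near 0.6, and 6/28 entity positives bound
their z at 1.92) — drops the z condition entirely and uses absolute
elevation over the panel's 10th-percentile cohort floor. Its labels are
`dual` (both panels), `signature` (entity panel only), `glioma` (glioma
panel only) and `outlier` (neither panel, and the sample's first-merge
height exceeds the 95th percentile of the cohort's first-merge heights;
quantiles are taken over the per-sample first-merge statistic because the
distribution of *all* merge heights is dominated by top-level cluster
joins, including the outlier's own).

Every reference sample must be called its own entity — a violated
anchor invalidates the run and raises a classification-integrity error
rather than a silent miscall. The `k = entities + 1` cut depth is a
declared convention (the visual read-off depth is unknowable); distance
ties in agglomeration follow the deterministic behavior of
`stats::hclust(method = "average")`, and tie configurations do not arise
in continuous synthetic data.

## Evaluation

Per marker probe, one-vs-rest ROC over the log2 normalized expression with
entity membership as the positive class; AUC is the trapezoidal area,
equal under the midrank tie convention to the Mann–Whitney U statistic
divided by `n_pos * n_neg` (verified exactly against a brute-force pairwise
oracle in the tests). Per-probe ROC is the primary output; a panel-mean
variant is exposed as an option. Entities without positive samples are
skipped with a warning — with a single positive sample the AUC is still
defined but fragile, which mirrors the rarest entity in the modeled cohort.

## Numerical and testing choices

* All randomness flows through explicit integer seeds
  (`withr::with_seed`); identical config + seed gives byte-identical
  outputs, including written RCC files.
* Sub-seeds are derived as `(seed + 7919 * offset) mod (2^31 - 1)` to stay
  in integer range.
* Problem sizes: discovery tests use 200–1000 probes at 20-vs-60 samples
  with 25–100 repetitions; recovery tests run 10–20 seeded 187-sample
  cohorts; oracle checks use 50 random instances at n ≤ 7 (clustering) and
  25 at n ≤ 30 (AUC). These sizes make the planted-truth comparisons
  statistically meaningful while keeping a full test run under a minute.
* Scale-invariance is asserted at relative tolerance 1e-12: multiplying
  counts by `k` perturbs `exp(mean(log(x)))` in the last ulp, so literal
  bit identity is not a property floating point can deliver.

## What the generators do not model

Synthetic cohorts demonstrate that the *pipeline* recovers what was
planted; they do not demonstrate performance on real tumors. Not modeled:
probe-specific hybridization affinity, fragment-length-dependent FFPE
degradation (only a scalar lane efficiency), tumor-cell-content dilution
(the >70% tumor-cell slide-review criterion is metadata only), correlated
marker co-expression within an entity (probes are conditionally
independent given the signature), cross-hybridization between related
transcripts, batch/cartridge effects, and methylation profiling itself.
Passing recovery tests therefore validates the statistical machinery and
its calibration, not clinical sensitivity.

## Known limitations

* The calling rule is a declared operationalization; other reasonable
  rules (probabilistic posteriors, per-entity adaptive cuts) are out of
  scope.
* The 200-repetition variant used for candidate-poor classes is exposed via
  `discovery_params(n_reps = 200)` but no other selection rule changes with
  it.
* Content normalization over all endogenous genes and cross-cartridge batch
  correction are intentionally absent.
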