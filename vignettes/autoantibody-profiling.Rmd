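---
title: "Serum autoantibody profiling on protein microarrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum autoantibody profiling on protein microarrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seroprofiler analyses high-throughput serum autoantibody screens on
full-length protein microarrays of the kind used for IgG reactivity
profiling in case/control cohorts: each slide carries ~hundreds to
thousands of recombinant human proteins spotted in technical
quadruplicate, a serum sample is hybridized per slide, and bound IgG is
read out as a fluorescence intensity per spot. This vignette documents
the models, parameters and design choices behind every stage; the README
shows a worked run.

```{r setup, eval = FALSE}
library(seroprofiler)
```

## The preprocessing model

The working unit throughout is the **log2 net intensity (RFU)**: for
each spot the local mean background is subtracted from the mean
foreground, negative or tiny nets are floored at `floor` (default 1 on
the linear scale, i.e. 0 after log2), and the result is log2
transformed. Subtract-then-log avoids logarithms of negative values,
and floored spots are marked so downstream consumers can see them.

Stages run in a fixed, provenance-recorded order:

1. **Net intensity** per spot, as above.
2. **Replicate CV filter.** The percent coefficient of variation
   (100·sd/mean) across a spot's technical replicates is computed on the
   *linear* net scale — CV is conventionally a linear-scale statistic —
   and groups above `cv_threshold` (default 20%) are excluded whole.
3. **Aggregation.** A retained cell is the mean log2 net RFU of its
   surviving replicates. Cells with fewer than two surviving replicates
   are treated as missing and imputed with the antigen median; every
   imputed cell is recorded in a mask on the matrix. Antigens missing in
   more than half the samples are excluded as `sparse`. Imputation keeps
   the matrix complete for the linear-model stage, but an imputed cell
   carries no measurement — which is why the mask exists (see NCF below).
4. **Polyspecific (PSA) sample detection.** Some sera carry low-affinity
   antibodies that bind a broad swath of antigens; such samples dominate
   heatmaps and carry no antigen-specific information. We operationalize
   the visual heatmap check as a *breadth* score: the fraction of
   antigens on which the sample exceeds the antigen's median + 3·MAD
   across samples. A sample is flagged when its breadth exceeds both the
   cohort's own robust bound (median + 3·MAD of breadth) and an absolute
   floor `psa_breadth_min` = 0.25. Antigens with zero MAD contribute no
   exceedances, so a perfectly homogeneous matrix flags nothing. Flagged
   samples are masked from **every** later computation — detection
   happens right after aggregation precisely so that broad-reactivity
   sera cannot distort the negative-control filtration statistics or the
   normalizations that follow.
5. **Negative-control filtration (NCF).** The array carries quadruplicate
   spots of a protein that does not react with sera. An antigen whose
   cross-sample profile merely tracks this control is reporting the
   sample-to-sample baseline (serum concentration, secondary antibody,
   scan intensity), not serology. Rather than a fixed correlation
   cutoff, the threshold is data-adaptive: the 5th percentile of the
   pairwise correlations among the control's own replicate profiles —
   "as similar to the control as the control is to itself". An antigen
   is excluded when its correlation with the mean control profile
   reaches that threshold **and** its median intensity lies below the
   75th percentile of the control intensity distribution; the intensity
   condition protects genuinely reactive antigens that happen to
   co-vary with the baseline. Correlations are computed over *observed*
   cells only (the imputed-cell mask), because a median-imputed cell is
   a constant that dilutes correlation estimates; with fewer than 8
   observed cells the antigen falls back to all cells. Constant antigens
   are excluded with reason `constant`.
6. **Cyclic loess normalization.** Every pair of samples (i, j) is
   normalized to each other: M = x_i − x_j is smoothed against
   A = (x_i + x_j)/2 with `stats::lowess` (span 0.7, 3 iterations) and
   half the fitted trend moves each side. The symmetric update preserves
   each antigen's grand mean exactly. Beyond 50 retained samples the
   full pair set (n(n−1)/2 pairs) is replaced by a seeded random draw of
   3n pairs per iteration, which bounds cost while still mixing all
   samples; the seed lives in the pipeline config so runs are
   reproducible.
7. **Batch correction.** Processing batches shift location and scale per
   antigen. Correction uses the ComBat empirical-Bayes model (additive
   and multiplicative batch effects shrunk toward batch-level priors)
   via `sva::ComBat`, preserving diagnosis, age and sex in the design.
   The wrapper enforces what ComBat assumes: at least 3 samples per
   batch, and no perfect aliasing between batch and a preserved
   covariate (the offending covariate is named in the error). A
   single-batch study passes through unchanged.

Every exclusion carries a reason, and the QC report reconciles exactly:
retained + excluded = tested.

## Differential testing

Per antigen we fit ordinary least squares on the design
(intercept, diagnosis, age, sex), with diagnosis coded case = 1 so a
fold change above 1 means higher in cases. Age and sex are adjusted
because case/control cohorts in this setting are typically imbalanced in
both; the test suite demonstrates that with planted age confounding the
adjusted model holds its nominal type-I error while the diagnosis-only
model inflates.

Residual variances are moderated by empirical Bayes: with per-antigen
residual variance s² on d degrees of freedom and a scaled inverse-chi²
prior (d0, s0²), the posterior variance is

  s̃² = (d0·s0² + d·s²) / (d0 + d)

and the moderated t = β̂ / (s̃·√v) has d0 + d degrees of freedom.
Hyperparameters are estimated by moment-matching the distribution of
log s² across antigens: the excess of var(log s²) over trigamma(d/2)
determines d0 through trigamma inversion (Newton iteration), and the
mean determines s0². When the observed spread is no larger than expected
under equal true variances, d0 = ∞ and all posteriors collapse to s0²
(with a warning in the degenerate all-equal case). The d0 = 0 limit
reproduces the ordinary t-test exactly and is machine-checked. No
robust or intensity-trend variants are offered — this is the simplest
published moderated-t, and the suite cross-checks it against the
reference implementation to machine precision.

Significance calls use the unadjusted p ≤ 0.05 (inclusive boundary), as
is common when no antigen survives multiple-testing correction in
modest cohorts; Benjamini–Hochberg adjusted values are always reported
alongside so the reader can see that. The BH step-up is implemented
directly (and verified against both a brute-force definition and
`p.adjust`) because it is part of the package's tested contract.

## Clinical-score and age correlations

`correlate()` is a validated wrapper over `stats::cor.test`
(product-moment r, two-sided p from the exact t transform), with
pairwise-complete handling and the used n reported per antigen.
Severity-score correlations are restricted to case samples that have a
score — in this design only a subset of cases is typically scored — and
age correlations use all retained samples. Significance counts mirror
the differential convention (unadjusted p ≤ 0.05).

## Cross-reactivity adjudication

Two antibodies that correlate strongly may be one antibody binding two
similar antigens. The screen proceeds in three steps:

1. **Correlation screen.** All unordered pairs of significant antigens
   with r² > 0.7. The threshold is interpreted as *squared*
   product-moment correlation (|r| > 0.837); reports in this field
   sometimes label plain r as "R²", and the squared reading is the
   literal, stricter one. It is configurable.
2. **Global alignment identity.** Needleman–Wunsch with affine gaps
   (BLOSUM62, gap open 10, gap extend 0.5 — EMBOSS-needle-like
   defaults; a gap of length L costs open + L·extend), implemented in
   C++ with deterministic tie-breaking on traceback (aligned pair
   preferred, then gap in the first sequence). Percent identity is
   identical positions over alignment length, gap columns included —
   the convention of standard alignment reports. Global rather than
   local alignment is used throughout because the quoted identity
   thresholds refer to whole-protein homology. The DP is verified
   against exhaustive alignment enumeration for short sequences and an
   independent aligner for longer ones.
3. **Isoform screen and verdicts.** Each significant antigen is aligned
   against the whole panel; hits above 50% identity get their profile
   correlation attached. The verdict rule is pure and total: a pair is
   `possible_crossreactivity` iff identity > 50% **and** r² > 0.7;
   high homology with uncorrelated signals, or high correlation between
   dissimilar antigens, both read `likely_biological`. Conformational
   mimicry is outside what sequence analysis can exclude, and the
   package does not claim otherwise.

## Set overrepresentation

A generic Fisher/hypergeometric overrepresentation on user-supplied
GMT sets replaces web-service enrichment: one-sided hypergeometric p per
term, BH FDR across tested terms, and reported terms need at least two
query members and FDR < 0.05. The background defaults to the
filtration-retained panel — the tested universe is the array content,
not the genome, and an array enriched for autoantigens would bias
genome-background p-values optimistically. The 2×2 exact test sums
hypergeometric probabilities not exceeding the observed table's (the
standard two-sided convention) and is verified against complete
enumeration for all small tables.

## The synthetic-data generator

Because raw serum-array studies of this kind are rarely deposited, the
package ships a truth-known generator whose defaults mirror the study
conditions the pipeline targets: 93 cases vs 28 controls (cases younger,
8.3 ± 2.3 vs 11.3 ± 2.1 years, and predominantly male, 73/93 vs 14/28),
400 antigens of which 25% are truly reactive, planted case/control
effects with |log2 FC| in [0.2, 1.2] (bracketing the ~0.7–1.7 ratio-scale
band such screens report, with a tail beyond 1 so power at the
|log2 FC| ≥ 1 benchmark is measurable), 15% of effects positive, two
processing batches (location +0.4 log2, scale ×1.15, with per-antigen
jitter), 9 polyspecific samples, and severity scores for ~54% of cases.

The intensity model is layered. A shared per-sample baseline factor
u_s ~ N(0, 0.4²) stands for serum IgG titer, dilution and scan session;
non-reactive antigens are baseline + small offsets (sd 0.1) + small
noise (sd 0.05) and therefore track the negative control, while reactive
antigens get antigen-specific elevations (1.5–4 log2 above baseline),
biological noise (sd 0.6) and only a weak baseline loading (0.2). Age
slopes (mean −0.02 log2/yr) and sex offsets apply to reactive antigens
only, emulating the declining autoantibody signal with age that such
cohorts show. PSA samples receive a ~3 log2 elevation on 90% of
antigens. The spot layer adds multiplicative log-normal replicate noise
(sdlog 0.12, i.e. ~12% CV — typical array precision and comfortably
under the 20% filter), log-normal local background, a 1% fraction of
noisy spots and 0.5% scanner-flagged spots. Batch shifts apply to every
spotted protein including the negative control, as a processing shift
physically would.

Three noise scales were calibrated once, during development, against the
planted-structure recoverability requirements (NCF retention/exclusion
≥ 90%, 9/9 PSA recovery with ≤ 1 false positive) and then frozen:
sigma_nonreactive = 0.05 (a non-reactive antigen has no serum binding,
so beyond the shared baseline its variation is technical),
non-reactive offset sd = 0.1 (non-reactive spots share one baseline
signal), and sdlog_spot = 0.12. The structural lever behind NCF is worth
stating: the data-adaptive threshold comes from *single-spot* control
profiles while antigen profiles are 4-spot means, so replicate-level
noise is exactly the margin that separates the two correlation
distributions.

What the generator does **not** emulate: image-level artifacts (spot
merging is re-assayed, not corrected, in practice), spatial
within-slide gradients, antigen-antigen biological correlation
structure beyond the shared baseline, isotype effects, and plate-edge
effects. Passing the simulation suite therefore shows the pipeline
recovers planted structure under this model, not that it is robust to
every failure mode of real slides.

## Numerical choices and degenerate inputs

* Tie-breaking in the aligner is fixed (see above), so outputs are
  byte-stable across runs and platforms.
* `lowess` against a constant A falls back to the mean of M; constant
  columns pass through cyclic loess unchanged.
* Zero-variance vectors are an error in `correlate` (undefined r), a
  `constant` exclusion in NCF, and a no-flag guard in PSA detection.
* The trigamma inversion uses the asymptotic branches 1/√y and 1/y
  outside [1e−6, 1e7] and Newton steps inside, to 1e−10 relative
  tolerance.
* All stochastic entry points (generator, loess pair subsampling) take
  explicit seeds and restore the caller's RNG state.

## Problem sizes used in the checks

The bundled verification suite runs, on one CPU in a few minutes: a
121 × 400 end-to-end study for filtration/PSA recovery; 200 Monte-Carlo
replicates of 500 null antigens for type-I calibration (adjusted vs
unadjusted); 40 replicates of 100 antigens at |log2 FC| = 1 for power;
one pure-shift batch simulation; enumeration oracles for alignments
(lengths ≤ 7; the alignment count grows like the Delannoy numbers, so
longer pairs are cross-checked against an independent aligner instead),
all 2×2 tables with margins ≤ 8, and 1,000 random BH vectors.

## Known limitations

* PSA detection is an operationalization of a visual check; its breadth
  floor (0.25) is a judgment calibrated on the synthetic scenario.
* The NCF threshold rests on as few negative-control replicate profiles
  as the array provides (here 4 → 6 pairwise correlations); arrays with
  more control spots would estimate it more stably.
* The moderated model handles one two-level diagnosis factor with
  numeric covariates; contrasts, interactions and mixed models are out
  of scope.
* Identity percentages are parameter-sensitive at the few-percent level;
  the defaults are stated and configurable, not canonical.
* The bundled reference panel for the identity checks is synthetic
  (built by copy-and-mutate at target identities); conclusions about
  real proteins require their real sequences.
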