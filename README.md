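# seroprofiler

Analysis of high-throughput serum autoantibody screens on full-length
protein microarrays. In these assays, each slide carries hundreds to
thousands of correctly folded recombinant human proteins spotted in
technical quadruplicate; a serum sample is hybridized per slide and
bound IgG is detected by a labelled secondary antibody, giving one
fluorescence intensity per spot. The package turns the resulting
GenePix-style spot tables into a quality-filtered antigen matrix and
takes it through differential testing, clinical-score correlation,
cross-reactivity adjudication and set overrepresentation. It is aimed
at analysts running case/control autoantibody discovery cohorts — for
example neurodevelopmental or autoimmune studies with unbalanced age
and sex between groups.

## What it computes

Preprocessing works on the **log2 net intensity** (RFU):
`log2(max(fg − bg, floor))` per spot, then

1. technical-replicate **CV filter** (linear-scale CV% > 20 excluded),
2. replicate **aggregation** to a samples × antigens matrix (with
   recorded median imputation of cells that lose their replicates),
3. **polyspecific-sample (PSA) detection** — sera reactive against a
   broad swath of antigens are flagged by a robust breadth score
   (fraction of antigens above the antigen's median + 3·MAD) and masked
   from all later stages,
4. **negative-control filtration (NCF)** — antigens whose cross-sample
   profile tracks the non-reactive control protein at least as strongly
   as the control's own replicates track each other (a data-adaptive
   threshold, not a fixed cutoff) and whose intensity sits in the
   control's range are excluded as carrying no serological signal,
5. pairwise **cyclic loess** normalization (grand mean per antigen
   preserved exactly),
6. **ComBat empirical-Bayes batch correction** preserving diagnosis,
   age and sex.

Differential testing fits, per antigen *g*,

    y_g = β0 + β1·diagnosis + β2·age + β3·sex + ε,   ε ~ N(0, σ_g²)

and moderates the residual variances by empirical Bayes:
`s̃² = (d0·s0² + d·s²)/(d0 + d)`, with the prior (d0, s0²) estimated by
moment-matching log s² across antigens (trigamma inversion); the
moderated `t = β̂1/(s̃√v)` has `d0 + d` degrees of freedom. Fold change
is `2^β̂1` (case/control, ratio scale). Calls use unadjusted p ≤ 0.05
with Benjamini–Hochberg FDR reported alongside.

Cross-reactivity screening asks whether two correlated autoantibody
signals (r² > 0.7) could be one antibody binding two similar antigens:
candidate pairs and panel isoforms are aligned globally
(Needleman–Wunsch, BLOSUM62, affine gaps 10/0.5, in C++) and a pair is
ruled `possible_crossreactivity` only when identity > 50% **and**
r² > 0.7. Enrichment is a hypergeometric overrepresentation test on
user-supplied GMT sets against the filtration-retained panel as
background.

A truth-known synthetic study generator (`sim_config()`,
`generate_study()`) emulates the whole data model — quadruplicate
spots, log-normal intensities, a negative-control protein, two
processing batches, planted case/control effects, age/sex confounding
and PSA sera — so every stage is validated against planted truth. See
the methods vignette (`vignettes/autoantibody-profiling.Rmd`) for the
models, parameter choices and limitations.

## Worked example

```r
library(seroprofiler)

cfg   <- sim_config(n_cases = 20, n_controls = 10, n_antigens = 60, n_psa = 2)
study <- generate_study(cfg, seed = 7)
pre   <- preprocess_study(study$spots, study$metadata, seed = 1)
pre$amat
#> <antigen_matrix> 30 samples x 60 antigens
#>   retained: 28 samples, 19 antigens
#>   antigen exclusions: ncf_excluded=41
#>   excluded samples: S018, S021
#>   provenance: net_intensity -> cv_filter(threshold=20) ->
#>     aggregate_replicates(imputed=91) -> detect_psa(flagged=2) ->
#>     negative_control_filter(threshold=0.7862) ->
#>     cyclic_loess(span=0.7,iterations=3) -> batch_correct(batches=2)
```

Both planted polyspecific sera (S018, S021) were flagged, and the 41
excluded antigens are the simulation's non-reactive ones — only
baseline-tracking signal, no serology. Differential testing on the
retained matrix:

```r
tab <- run_differential(pre$amat, study$metadata)
head(as.data.frame(tab)[, c("antigen", "FC", "log2FC", "t", "p", "adj_p", "call")], 5)
#>   antigen        FC     log2FC         t          p     adj_p call
#> 1  Ag0010 1.8846608  0.9143049  2.713511 0.01162566 0.1585212   up
#> 2  Ag0044 1.4414918  0.5275627  2.455095 0.02104625 0.1585212   up
#> 3  Ag0019 0.8781517 -0.1874580 -2.377445 0.02502966 0.1585212 down
#> 4  Ag0030 0.6754995 -0.5659735 -1.945371 0.06255718 0.2556457   ns
#> 5  Ag0036 1.3991122  0.4845116  1.827048 0.07913029 0.2556457   ns
```

`FC` is the case/control ratio (`FC > 1`: higher in cases), `p` the
moderated-t p-value and `call` the p ≤ 0.05 decision; as typical for a
cohort this small, no antigen survives BH correction (`adj_p`).
`correlate_matrix(pre$amat, study$metadata, "age")` then reports the
per-antigen age correlations with pairwise-complete n.

The one-call orchestration `run_all()` reads GPR/GAL/metadata from
disk and writes `matrix.tsv`, `qc.json`, `diff.tsv`, `assoc.tsv`,
`xreact.json`, `enrich.tsv` and a reconciling `manifest.json`; a thin
command-line wrapper lives at `inst/cli/seroprofiler.R`.

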