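---
title: "Deriving proliferation-type prognostic signatures: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving proliferation-type prognostic signatures: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapsig)
```

This vignette is the package's own account of the statistics it implements:
what each stage assumes, which knobs matter, what the synthetic-data module
does and does not emulate, and where we made judgement calls the published
workflow leaves open.

## The two-stage design

The pipeline reconstructs a two-stage derivation. A two-condition cell-line
contrast (an oncogene-transfected line against its vector control, on
duplicated arrays hybridized with RNA pooled from three independent lines)
nominates candidate genes. A survival-annotated tumour cohort then reduces
the candidates to a signature — deliberately *without* looking at outcomes —
and only the finished classifier is evaluated against survival. The
outcome-blindness is enforced structurally: no function before
`evaluate_survival()` accepts clinical data, so the reduction cannot leak
survival information even by accident.

## Cell-line stage

**Intensity filtration.** Probes near the detection floor disagree wildly
between replicate arrays and would poison any downstream statistic computed
from two arrays per condition. We label a probe *reproducible* when its
between-replicate log2 ratio stays within `concordance_bound` (default
`log2(1.5)`, i.e. 1.5-fold) in every replicate pair, and scan the probe's
maximum intensity over those arrays as a one-dimensional classifier of that
label, choosing the cutoff that maximizes Youden's J over the observed
intensity percentiles. Two details matter. First, the classifier scores the
*maximum* intensity because the filter retains probes above the cutoff in at
least one array — classifier and filter must threshold the same statistic,
otherwise retention is systematically more permissive than the ROC analysis
claims. Second, the original multi-step filtration is published only by
citation, so this is a reconstruction of its intent, not a port; the spirit
(a ROC-estimated intensity cutoff against replicate concordance) is
preserved, the exact steps are not known. Degenerate inputs fall back
conservatively: if every probe (or none) is reproducible the smallest
candidate cutoff is returned and nothing meaningful is filtered.

**SAM screen.** On log2 intensities, each probe gets
`d = (mean_cond − mean_ctrl)/(s + s0)`, with `s` the pooled standard error
(2 degrees of freedom per group at the 2+2 design) and `s0` a fudge factor
damping small-variance probes, by default the median of the `s_i`. The
original coefficient-of-variation minimization for `s0` is unstable with two
pooled replicates, so the policy is pluggable (`s0_policy` accepts a number
or a function) and the simplification is deliberate.

With 2+2 arrays there are exactly `choose(4, 2) = 6` distinct relabelings,
enumerated exhaustively — sampling would be pointless. Two of the six (the
observed grouping and its complement) preserve the contrast: under a real
effect their permuted d statistics carry the full signal. With thousands of
permutations this contamination is a negligible `O(1/B)` correction and
standard SAM ignores it; at `B = 6` it puts one third of any true signal
into the null expectation. We measured the consequence directly during
development: expected order statistics computed over all six relabelings
compress the observed-minus-expected deviations by a factor of about 2/3 and
collapse the screen's sensitivity. The null reference (both the expected
order statistics and the expected-false counts) therefore uses only the four
contrast-breaking relabelings; all six are still enumerated and reported.

Calling uses the classic cut-point rule: sorting the observed d against the
expected order statistics, the first position on each side of the origin
whose deviation reaches `delta` defines a d threshold, and *every* probe
beyond it is called. (Calling band exceedances position-by-position instead
would un-call probes more extreme than the cut and make the call set
non-monotone in d.) The expected number of false calls at a cut is the mean
over the null relabelings of their exceedance counts: with four relabelings
the median of small integer counts is zero-inflated, and a spurious exact
zero at an extreme delta would otherwise always win the minimization below.

`delta` is selected to minimize the estimated FDR among deltas calling at
least one probe, smallest delta on ties — the published selection rule. The
rule has a documented weakness we chose not to paper over: minimizing a
noisy ratio over a grid picks downward noise, so under a *complete null* the
estimated FDR at the selected delta is optimistic (the realized
false-discovery proportion there is 1 by construction — every call on null
data is false — while the estimate averages well below that; the acceptance
suite measures this honestly and the corresponding check documents the gap).
At a fixed delta the estimate is unbiased, and with genuine signal the
minimum lands where the call set is large and clean, which is the regime the
procedure was designed for.

Significance finally requires the two-sided linear fold cutoff
(`fold_cutoff = 2`: fold ≥ 2 or ≤ 0.5) *and* the SAM call. Folds are ratios
of linear-scale means while d works on log2 values — the MAS5-era
convention. Down-regulation is retained on equal terms with induction.

## Cohort stage

**Normalization and collapsing.** Raw cohort intensities are divided by the
per-probe median across the cohort (or across each subgroup when subgroup
normalization is requested) and log2-transformed; probe-level rows are then
averaged per gene. The order — normalize on probes first, average per gene
second, both on the log scale — is fixed and test-asserted; the published
description normalizes per probe set and averages "for each patient sample"
afterwards, but does not state the scale, so averaging on the log scale is a
documented assumption. For even sample counts the raw-scale median is the
arithmetic mean of the two middle order statistics (the usual convention);
note that on the log2 scale the median of the normalized values is then not
exactly zero but sits within the concavity gap of the two middle values —
only odd-sized groups centre exactly. Missing values are rejected outright:
the source workflow states no imputation rule, and inventing one silently
would change every downstream statistic.

**Uniform-gene elimination.** Genes with cohort-wide IQR below
`spread_threshold` (default 0.5 log2 units, i.e. 1.4-fold between quartiles)
carry no stratifying information and are removed. In the original derivation
this step dropped 87 of 254 genes; the synthetic cohort plants a comparable
fraction of near-constant genes so the step has something real to do.

**Patient partition.** k-means with `k = 2` (predetermined, as published) on
patients in normalized gene space, squared-Euclidean, best of `n_restarts =
50` seeded random starts. The published analysis is ambiguous about whether
clustering used the full differential set or the post-elimination set; we
default to the post-elimination set (clustering on genes just declared
uninformative seemed indefensible) and expose
`use_all_genes_for_kmeans = TRUE` for the other reading. The *expressor*
cluster is the one with the higher mean over the candidate genes — the
orientation rule is ours, chosen because the signature genes are reported as
up-regulated in the poor-prognosis class; the source states no explicit
rule.

**Gene selection.** Per gene, a variance-ratio F test at 0.05 chooses the
t statistic (pooled when variances look equal, Welch otherwise) and genes
with two-sided t p-value < `alpha = 0.05` survive. The published workflow
"entered" F-test results into the t-tests without elaboration; the
variance-guided choice is the standard reading of that phrase. No
multiple-testing correction is applied at this stage, replicating the
original; `bh_correct = TRUE` provides Benjamini-Hochberg for users who want
it. Ward hierarchical clustering (`ward_gene_order()`) is provided solely
for display ordering and gates nothing.

**AUC ranking.** Each surviving gene is scored as a single-feature
classifier of the partition by the empirical Mann-Whitney AUC — explicit
enumeration of between-cluster pairs with half credit for ties. The original
used a proper-binormal fitting program (PROPROC); its likelihood is not
reproduced here. For well-separated genes at cohort sample sizes the
empirical and proper-binormal AUCs agree closely, the empirical version is
assumption-free, and the routine is pluggable (`auc_fun`) for anyone wanting
to substitute a parametric fit. Genes with oriented AUC strictly above
`auc_cutoff = 0.95` form the signature, ordered by AUC with alphabetical
tie-break; down-oriented genes are recorded and sign-flipped at scoring
time. The published equation of AUC > 0.95 with "probability of error under
5%" conflates AUC with accuracy; we note it and do not compute it.

**Scoring.** A patient's score is the mean of the available signature
genes' normalized values; `score > 0`, strictly, classifies MAPS+. A
platform lacking some signature genes (the validation scenario — one gene
absent there in the original study) scores on the remainder and reports
`n_genes_used`. A patient exactly at the cohort median on every signature
gene scores 0 and is deliberately MAPS−.

## Survival machinery

Kaplan-Meier, log-rank and Cox are implemented in the package (the CRAN
`survival` package serves as an independent oracle in the test suite, never
as the implementation). Choices: months as the time unit and 5-year survival
read off the KM step function at 60 months; Greenwood variance; censorings
at an event time count as at risk for that event. The log-rank statistic is
the Mantel-Haenszel chi-square with 1 df. Cox maximizes the Efron-corrected
partial likelihood by Newton-Raphson (Breslow available; the two coincide
exactly on tie-free data) with step-halving, convergence when the
log-likelihood moves < 1e-9 and the gradient < 1e-6, a hard stop at 50
iterations, and flagged errors for constant covariates and monotone
likelihoods (|beta| > 20 — complete separation has no finite MLE and
reporting one would be worse than failing). Efron is the default because
clinical follow-up recorded in months produces heavy ties. Standard errors
come from the inverse observed information; p-values are Wald. Patients with
unknown covariate values are dropped per-model, complete-case, with a
logged count. Disease-free survival needs no special support: any
time/event pair runs through the same machinery.

## What the generators emulate — and what they do not

`simulate_cell_line_arrays()` produces duplicated two-condition arrays:
well-measured probes at log2 intensity ~N(10, 1) with replicate noise 0.12
log2 units (pooling RNA from three lines averages biological noise down —
this is the stated rationale for the small default), planted two-sided fold
changes at 2.5-fold, and a low-intensity background population at the
detection floor (log2 ~N(5, 0.4), replicate noise 0.8) representing
unexpressed transcripts whose "signal" is array noise — the population the
filtration stage exists to remove. Noise is lognormal on the raw scale
(Gaussian in log2), the standard microarray model.

`simulate_cohort()` plants a one-factor proliferation module: a latent
factor z follows a two-component Gaussian mixture (weights 0.5/0.5, means
∓1, SDs 0.5) so a genuine 2-cluster structure exists for k-means to find;
module genes load on z with 1.0 log2 units against residual noise of 0.5
(within-module correlation ≈ 0.83 by the one-factor closed form, comfortably
above the 0.6 regime the recovery properties assume); the death hazard is
`baseline_hazard · exp(beta_z z + beta_T T + beta_N N)` with exponential
baseline 0.01/month, `beta_z = log 2`, and stage/node effects matching the
magnitudes reported for such cohorts (HR 2.6 and 2.8); binary covariates
correlate with z at odds ratio 1.5 so multivariate adjustment is a real
test, with marginal prevalences echoing a stage I–III adenocarcinoma case
mix; grade carries no hazard effect (it was not independently prognostic in
the source analysis). Censoring is administrative at a Uniform(0, τ)
horizon with τ calibrated by root-finding to the requested censoring rate
(default 0.4). Default sizes are the study's: 441 patients, 254 candidate
genes, a 7-gene module named after the canonical proliferation genes, and a
34% uniform-gene fraction.

What passing tests on these simulations do *not* show: the generators draw
independent Gaussian noise per gene — no correlated non-module expression
programs, no batch or site effects, no probe-level artifacts (PM/MM, spatial
defects), no platform mismatch beyond the absent-gene scenario, no
informative censoring, and proportional hazards hold exactly by
construction. Real cohorts violate several of these at once; recovery rates
here are upper bounds on what identical settings would achieve in the wild.

## Numerical and reproducibility notes

Every stochastic step (generators, k-means restarts) runs under an explicit
seed through a helper that restores the caller's RNG state, so a fixed
configuration reproduces byte-identical output files; reports carry the
seed and an MD5 hash of the configuration for provenance. The delta grid
defaults to 50 equally spaced values over the observed deviation range —
fine enough to track the FDR curve, coarse enough not to chase noise.
Problem sizes used by the test and acceptance suites (4,000-probe arrays,
441-patient cohorts, 20-seed recovery sweeps, 100-replicate null
calibrations, 500-replicate Cox type-I checks) were chosen as the smallest
sizes at which the asymptotic claims they exercise are expected to hold.

## Known limitations

* The delta-minimization rule inherits the optimism of minimizing a noisy
  estimate; its FDR at the chosen delta should be read as a lower bound,
  especially when few probes are called (measured honestly by the acceptance
  suite, see above).
* Two arrays per condition leave 2 df for variance estimation; the screen
  leans on `s0` and the fold cutoff, and no `s0` policy can rescue probes
  whose replicate noise rivals the planted effect.
* The empirical AUC is used where the original fitted a proper-binormal
  model; rankings can differ for genes near the cutoff.
* No missing-value support, no competing risks, no proportional-hazards
  diagnostics, no enrichment analysis (the original's pathway analysis used
  a proprietary knowledge base and is out of scope).
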