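---
title: "Beta-binomial penetrance estimation with covariate-calibrated priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-binomial penetrance estimation with covariate-calibrated priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Penetrance — the probability that a heterozygote for a variant manifests
the disease — is the natural clinical quantity for incompletely penetrant
dominant conditions, but for rare diseases the raw affected fraction is
dominated by sampling noise: most variants are observed in one or a few
heterozygotes, so the observed penetrance is almost always exactly 0 or 1.
`penbayes` treats each variant's affected count as binomial in an unknown
penetrance and places a beta prior over that penetrance, giving closed-form
conjugate posteriors throughout. The model is fitted in two stages: a
single *empirical* prior shared by all variants, then *variant-specific*
priors calibrated from covariates by a fixed-point (EM-style) scheme.

```{r}
library(penbayes)
```

## Evidence weights

Every ensemble computation weights variant `i` by
`w_i = 1 - 1/(0.01 + n_i)` where `n_i` is the total heterozygote count.
A singleton gets `w ~ 0.0099`, ten heterozygotes `w ~ 0.9`, and the weight
approaches 1 from below. The literal formula is negative at `n = 0`, so the
weight is clamped to `[0, 1]` and variants with no observed heterozygotes
are excluded from fitting — they receive prospective (prior-only)
estimates instead. A gentler ramp `1 - 1/(1 + 0.01 n)` is available as
`evidence_weight(form = "gentle")` for sensitivity analyses; it is not the
default because it leaves even 100-heterozygote variants with half weight.

## The empirical prior

The prior mean is the `w`-weighted average of observed penetrance
(`weighted_prior_mean()`), with weights normalized inside the average so
the result is a genuine mean. The concentration `nu = alpha + beta`
controls how strongly individual variants are shrunk and is not pinned
down by the mean alone. We choose `nu` to minimize a weighted
cross-validated squared error in which each *heterozygote* is predicted by
the beta-binomial posterior built from the variant's remaining counts and
the shared prior:

```
f1_i = (alpha_i - 1 + mu nu) / (n_i - 1 + nu)   # held-out affected
f0_i = (alpha_i     + mu nu) / (n_i - 1 + nu)   # held-out unaffected
MSE(nu) = sum_i w_i [ alpha_i (1 - f1_i)^2 + beta_i f0_i^2 ] / n_i / sum_i w_i
```

This form matters. The seemingly natural alternative — scoring the full
conjugate posterior against the observed penetrance — is strictly monotone
in `nu`: the posterior reproduces the observed fraction exactly as
`nu -> 0`, so that criterion is always "minimized" by no shrinkage at all
and cannot identify a concentration. The per-heterozygote hold-out version
is a proper squared-error criterion: the posterior predictive mean under
the *true* prior is the Bayes-optimal predictor of a held-out observation,
so the population minimizer is the generative concentration. On synthetic
Beta(2, 8)-binomial tables (2,000 variants, totals `1 + Poisson(20)`) the
fitted mean lands within ±0.01 of 0.2 and `nu` within about 5% of 10.

By default the prior mean entering variant `i`'s predictions also excludes
variant `i` (`loo = TRUE`), removing the remaining self-fit path; with
thousands of variants the two settings are nearly indistinguishable, and
the in-sample option is kept for comparison. Minimization is bounded
golden-section search on `log(nu)` over `[0.1, 1e4]` with tolerance 1e-6,
falling back to a 400-point log-spaced grid (with a warning) if the
optimizer fails. A joint free-(mean, nu) Nelder–Mead fit is available via
`joint = TRUE`.

## EM calibration of variant-specific priors

`em_fit()` initializes per-variant responses at the empirical posteriors
and iterates three steps until no fitted prior mean moves by more than
`tol` (default 1e-6, cap 100 iterations):

1. **Regression.** Weighted least squares of `logit(response)` on the
   covariates (responses clipped to `[1e-4, 1 - 1e-4]` first). Covariates
   are standardized with weighted moments; missing values are mean-imputed
   and accompanied by a missingness-indicator column; zero-variance and
   collinear columns are dropped with a warning.
2. **Prior mapping.** Fitted means `p_hat_i` become variant priors
   `(p_hat_i nu, (1 - p_hat_i) nu)`, with `nu` carried unchanged from the
   empirical prior: the ensemble's uncertainty scale is calibrated once,
   and only the means are recalibrated per variant. Consequently
   `alpha_EM,i + beta_EM,i = nu` for every variant.
3. **Refresh.** Responses are recomputed as conjugate posteriors of the
   new priors with the observed counts.

A linear fit on the logit scale was chosen over beta regression for
stability inside the fixed-point loop — it is closed-form, cannot fail to
converge within an iteration, and behaves well at the near-0/near-1
responses that dominate rare-disease tables. One correction is required:
least squares on the logit scale is mean-biased (by Jensen's inequality
the inverse-logit of a fitted mean underestimates the mean of the
inverse-logits when the response distribution is right-skewed), which
would let the whole prior ensemble drift below the empirical prior mean —
on pure-noise covariates we measured a systematic offset of about 0.04.
Each iteration therefore recenters the intercept (a one-dimensional root
solve) so that the evidence-weighted mean of fitted prior means equals
that of the responses. Under pure-noise covariates every variant prior
then stays within ±0.02 of the empirical prior mean, while slopes are
untouched.

Because regression weights are the evidence weights, a singleton shifts
its own fitted prior by well under 1% relative to leaving it out entirely:
known-benign and known-pathogenic heavily observed variants anchor the
calibration, and private variants inherit it.

The default covariate set is `{density, revel, alphamissense, clinvar}`
(ClinVar encoded 1 for P/LP, 0 for VUS and B/LB, missing when absent —
matching the clinical convention of treating VUS as unaffected for
evaluation). Any subset may be selected; covariates that are entirely
missing are dropped by `run_pipeline()`.

## Structural disease density

`compute_density()` summarizes the affected-heterozygote burden in each
residue's 3D neighborhood: the evidence-weighted affected fraction among
heterozygotes of variants whose residues lie within `radius` angstroms
(Cα–Cα) of the residue, its own variants included. The default radius is
15 Å with a uniform cutoff kernel; an exponential-decay kernel
(`exp(-d / length_scale)`) is available where a hard shell is too coarse.
Residues whose neighborhood carries no heterozygotes are `NA` (distinct
from a genuine density of 0, which means heterozygotes but no affected
ones). The ratio construction bounds the density in `[0, 1]` termwise.

When the density serves as an EM covariate it is computed in
leave-self-out mode (`density_covariate(leave_out = TRUE)`): the variant's
own heterozygotes are removed from both sums at its residue, so the
covariate carries only neighborhood information. Because a variant's
kernel weight at its own residue is exactly 1, the hold-out is a constant-
time subtraction from the precomputed sums — verified against an explicit
all-pairs re-computation in the test suite. For prospective (final)
estimates the all-data mode is used. Variants at unresolved residues are
flagged in a coverage report and their covariate is imputed with the
weighted mean density.

Density is computed on a single protomer chain; for homotetramers such as
the ryanodine receptor an inter-protomer neighborhood can matter near
interfaces, and a minimum-distance-across-chains mode is a straightforward
extension (not the default, since author-numbered protomer chains are the
common case and cross-chain residue numbering is frequently inconsistent).

## Hot-spot scanning

`scan_hotspots()` slides a 100-residue window over the protein and flags
windows holding more than 3 variants whose variant-bearing residues
average (strictly) above 0.4 penetrance; overlapping or adjacent
qualifying windows merge into maximal segments trimmed to their outermost
variant-bearing residues. The window mean is taken over variant-bearing
residues only — under the all-residue (diluted) reading, available as
`dilute = TRUE`, a tight cluster of half a dozen high-penetrance variants
could never lift a 100-residue mean above 0.4, which contradicts how such
clusters are reported in practice.

Two plausible-sounding invariants are deliberately *not* asserted, because
the merge-and-trim rule falsifies them: a merged segment's overall mean
can dip below the window threshold (two qualifying windows sharing their
high-value residues), and tightening a threshold can split one merged
segment into two, increasing the segment *count*. The invariants that do
hold, and are enforced in tests against exhaustive enumeration: every
trimmed segment contains at least one full qualifying window's variants,
and tightening either threshold produces segments nested inside the looser
ones with non-increasing total coverage.

The shipped domain map (`ryr2_domains()`) carries the five published
schematic ranges with positional labels; annotation labels anything
outside them "inter-domain".

## Evaluation conventions

- **Outcomes.** Brier scores and weighted Spearman correlations are
  computed against the empirical posterior (the best observation-only
  estimate); ROC and PR AUC against the binary label "at least one
  affected heterozygote". A posterior-threshold labeling rule is exposed
  as an alternative since the binary reduction is not unique.
- **Weighted Spearman** is the weighted Pearson correlation of mid-ranks
  (average ranks on ties), reducing to classical Spearman at equal
  weights.
- **ROC AUC** uses the Mann–Whitney concordance formulation (ties count
  one half), which the tests pin to an all-pairs count and cross-check
  against an independent ROC implementation. **PR AUC** is the step-wise
  average-precision estimator with tied scores entering as one threshold
  step; its null expectation is the positive prevalence.
- **Confidence intervals** are percentile bootstrap with stratified
  resampling (positives and negatives separately), 2,000 resamples by
  default, seeded.
- **Stratification.** Metrics are reported for all variants and for the
  rare stratum (allele frequency below 1% or unknown).
- **Cross-validation.** `loocv_evaluate()` refits the empirical prior and
  EM model without each variant and predicts its prior from covariates
  alone. `kfold_evaluate()` (default `k = 5`) assigns folds by sorted
  variant key before seeding, so fold membership is invariant to input
  row order; held-out posteriors are scored against empirical posteriors
  by weighted Spearman, per fold and pooled.

## The synthetic-data generator

`generate()` emulates the statistical structure the model assumes, with a
known truth retained for recovery tests: baseline penetrance
`Beta(1, 60)` (a rare-disease scale with heavy mass near zero), shifted on
the logit scale by latent standard-normal covariates (default slopes 1 on
two scores) and by Gaussian positional bumps at three loci (to exercise
the density and hot-spot machinery); stored scores are noisy probit
transforms of the latents (noise sd 0.5), so covariates correlate with but
do not determine the truth; heterozygote totals are 60% singletons and
otherwise `1 + Poisson(20)`, reproducing the U-shaped observed-penetrance
histogram of curated rare-variant tables; affected counts are binomial.
ClinVar-style labels are assigned from true penetrance with 15% label
noise for half the variants. Defaults (2,000 variants over 500 residues)
run the full pipeline in seconds; all generation is a pure function of the
configuration and seed.

`generate_toy_structure()` grows a self-avoiding 3D chain (3.8 Å bonded
spacing, 4 Å exclusion for non-consecutive residues) writable as PDB, so
the structure reader and density module are exercised end to end without
real coordinates.

What the generator does *not* emulate: literature ascertainment bias
beyond singleton-heavy totals, compound heterozygosity, relatedness among
carriers, coordinate mismatches between structure and transcript
numbering, and real protein geometry. Passing recovery tests therefore
demonstrate correctness of the estimator under the stated model, not
robustness to those real-data pathologies.

## Problem sizes and numerical choices

The test-suite and acceptance script use 2,000-variant tables for
prior-recovery and null checks, 1,000-variant tables across 20 seeds for
EM sign-recovery, 50-residue toy structures over 100 random
configurations for the density oracle, and maps up to 500 residues for
the hot-spot oracle — sizes at which every oracle comparison is exact and
the whole suite runs in well under a minute of compute per module.

Numerical details: probabilities are clipped at `1e-4` before logit
transforms; rank ties use mid-ranks everywhere; conjugate arithmetic is
validated against a beta-function-ratio oracle to 1e-12; estimate CSVs are
written sorted with fixed 6-decimal formatting so reruns are
byte-identical; B-factor export uses the sentinel -1.0 for unmapped
residues (PDB B-factor precision limits round-trips to 2 decimals).

## Limitations

Estimates inherit the biases of the input curation: population-database
carriers are presumed unaffected, and case reports over-sample severe
presentations. The model targets penetrance only — not prognosis, age of
onset, or treatment response — and the EM calibration is a fixed-point
scheme on posterior means, not a full joint likelihood: its convergence is
monitored (trajectory of maximum changes, with a flag if the cap is hit)
rather than guaranteed. Enumerating SNV-reachable substitutions requires
the coding sequence of the transcript of interest, which is deliberately
an input rather than a bundled asset.
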