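# penbayes

Continuous Bayesian estimation of disease penetrance for rare missense
variants, built for gene–disease pairs like *RYR2*–CPVT where most variants
have been seen in only a handful of heterozygotes.

## The problem

For a rare dominant disease, the penetrance of a variant — the probability
that a heterozygote manifests the phenotype — is the quantity clinicians
actually need, but the raw estimate `affected / (affected + unaffected)`
is useless for the "private" variants that matter most: with one or two
observed carriers it is always 0 or 1. `penbayes` shrinks those noisy
fractions with a beta-binomial empirical Bayes model and then calibrates a
*variant-specific* prior from covariates (in-silico scores such as REVEL
and AlphaMissense, ClinVar class, and a 3D structural disease-density
feature), so that unobserved variants get usable prospective estimates.

## The model

For variant *i* with `α_i` affected and `β_i` unaffected heterozygotes:

- **Observed penetrance** `p_i = α_i / (α_i + β_i)`.
- **Evidence weight** `w_i = 1 − 1/(0.01 + n_i)` with `n_i = α_i + β_i`,
  so singletons carry ~0.01 weight and well-observed variants ~1.
- **Empirical prior** `Beta(a, b)`: the mean `a/(a+b)` is the
  `w`-weighted average of observed penetrance; the concentration
  `ν = a + b` minimizes the weighted cross-validated squared error of
  held-out per-heterozygote predictions.
- **Empirical posterior** (conjugacy):
  `(α_i + a) / (α_i + β_i + a + b)`.
- **EM calibration**: iterate (1) weighted regression of the current
  point estimates on covariates (logit scale, mean-anchored), (2) map
  fitted means `p̂_i` to variant priors `Beta(p̂_i ν, (1−p̂_i) ν)`,
  (3) refresh the point estimates by conjugate update with the observed
  counts, until no fitted mean moves by more than `tol`.
- **Bayesian posterior**
  `(α_i + p̂_i ν) / (α_i + β_i + ν)`, with equal-tailed 95% credible
  intervals from the beta shape.

Around the core model the package provides the structural disease-density
covariate (evidence-weighted affected fraction within a 15 Å Cα
neighborhood, with a leave-self-out mode for leakage-free use as a
covariate), sliding-window hot-spot detection (mean penetrance > 0.4 over
a 100-residue span holding more than 3 variants), and probabilistic
evaluation: Brier score, weighted Spearman rank correlation, ROC/PR AUC
with stratified bootstrap CIs, leave-one-out and k-fold cross-validation.
A synthetic-data generator reproduces the statistical structure of curated
rare-variant tables (beta-distributed penetrance, covariate effects,
singleton-heavy totals, positional clusters, a toy 3D chain) so every
stage is testable without external data.

## Worked example

```r
library(penbayes)
counts <- system.file("extdata", "example_counts.csv", package = "penbayes")
tab    <- finalize_counts(read_count_table(counts))

observed_penetrance(14, 10)     # R420W: 14 of 24 heterozygotes affected
#> 0.5833333

prior <- fit_empirical_prior(tab)
prior
#> Beta prior: alpha = 0.7206, beta = 1.742 (mean 0.2926, concentration 2.463)

fit <- run_pipeline(tab, covariates = c("revel", "alphamissense", "clinvar"))
head(fit$estimates[, c("variant", "prior_mean", "posterior_mean",
                       "ci_low", "ci_high")], 4)
#>    variant prior_mean posterior_mean  ci_low ci_high
#> 1  p.R420W     0.7147         0.5956 0.40683   0.771
#> 2  p.V186M     0.0413         0.0433 0.00153   0.148
#> 3 p.R2258C     0.0470         0.0520 0.00192   0.175
#> 4 p.I3995V     0.0767         0.1136 0.00528   0.353
```

The covariate-calibrated prior pulls the heavily observed, high-scoring
R420W toward a high prior mean (0.71), while the singleton-weighted,
low-scoring V186M — despite its traditional "hot-spot" location — sits
near 0.04; the posterior blends each prior with the observed counts and
the credible interval reflects how many heterozygotes back it up.

A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "penbayes.R", package = "penbayes"))') \
    simulate --seed 7 --out sim/
```

with subcommands `simulate`, `ingest`, `density`, `fit`, `predict`,
`hotspot`, `evaluate`, each writing its outputs plus a JSON run manifest.

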