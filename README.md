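# allelescore

Allele scores (genetic risk scores) as instrumental variables for Mendelian
randomization, together with a Monte Carlo engine for studying when they
work and when they fail.

## The problem

Mendelian randomization estimates the causal effect of a continuous risk
factor X on a continuous outcome Y from observational data by using genetic
variants as instruments: variables associated with X but, if the
instrumental-variable assumptions hold, not with confounders or with Y
except through X. With many variants of individually small effect, the
conventional multivariable estimators run into *weak-instrument bias*:
two-stage least squares (2SLS) with one first-stage coefficient per variant
over-fits chance covariation between the variants and confounders, and its
estimates are pulled towards the confounded observational association, with
confidence intervals that under-cover badly.

An **allele score** collapses the J variants into a single instrument

  S_i = Σ_j w_j G_ij,

where G_ij ∈ {0, 1, 2} is individual i's dosage of risk-factor-increasing
minor alleles and w_j are weights — all ones (unweighted), estimated
internally, cross-validated, or taken from an external source. A single
strong instrument (first-stage F near 60 in the reference design, versus
about 3 per-variant) removes the over-fitting, so the score-based IV
estimate is median-unbiased with nominal coverage — *provided every variant
in the score is a valid instrument and the score is constructed without
peeking at the analysis data*.

The package provides:

* **Simulation** (`sim_config()`, `build_architecture()`,
  `simulate_genotypes()`, `simulate_dataset()`) — a configurable generating
  model: X is a linear sum of variant effects, an unmeasured standard-normal
  confounder U and noise; Y = β_X X + U + noise. Scenario variants cover
  unequal effect sizes, major-gene/polygene architectures, non-linear
  (heterozygote-deviation) effects, variant–variant and variant–covariate
  interactions, and pleiotropic invalid instruments that act on U instead
  of X.
* **Scores** (`unweighted_score()`, `estimate_weights()`,
  `internal_weighted_score()`, `cv_weighted_score()`,
  `external_weighted_score()`, `select_variants()`) — every weighting
  procedure above, plus data-driven variant selection (top-k or P-value
  threshold) for quantifying winner's-curse bias.
* **Estimators** (`score_iv()`, `two_stage_least_squares()`,
  `liml_estimate()`, `k_class()`, `composite_iv()`, `ols_estimate()`,
  `first_stage_f()`) — allele-score IV, multivariable 2SLS, LIML (k-class
  with the closed-form λ_min), the composite main-variants-plus-score
  estimator, and the observational benchmark.
* **Study engine** (`mr_method()`, `run_cell()`, `run_table()`,
  `summarize_estimates()`, `write_manifest()`) — paired Monte Carlo
  comparisons reporting mean first-stage F, median estimate, IQR, empirical
  coverage of 95% intervals and power, with deterministic per-replicate
  seeding and bit-for-bit reproducible manifests.

## A worked example

```r
library(allelescore)
set.seed(2025)
cfg <- sim_config(beta_x = 0.2)        # n = 3000, J = 25, MAF 0.3, true effect 0.2
dat <- simulate_dataset(cfg)

ols_estimate(dat$x, dat$y)
#> IV estimate (ols): beta = 0.6896 (SE 0.0156), 95% CI [0.6590, 0.7203]

score_iv(unweighted_score(dat$genotypes), dat$x, dat$y)
#> IV estimate (score_iv): beta = 0.2921 (SE 0.1375), 95% CI [0.0227, 0.5615]
#>   first-stage F = 47.9 on 1 instrument(s), n = 3000

two_stage_least_squares(dat$genotypes, dat$x, dat$y)
#> IV estimate (tsls): beta = 0.4570 (SE 0.1032), 95% CI [0.2548, 0.6592]
#>   first-stage F = 3.0 on 25 instrument(s), n = 3000
```

The observational slope (0.69) is badly confounded: the true effect is 0.2.
The allele score, a single instrument with F ≈ 48, recovers it (0.29 ± 0.27,
interval covering 0.2). Multivariable 2SLS, with 25 instruments at F ≈ 3,
lands between truth and the confounded slope — weak-instrument bias in one
dataset. Averaging over many datasets makes the pattern exact:

```r
run_table(sim_config(seed = 2025, n_reps = 200),
          methods = list(mr_method("score"), mr_method("tsls"), mr_method("liml")),
          betas = c(0, 0.2))
#>   scenario              method beta mean_F   median   IQR coverage_pct power_pct ...
#> 1  initial    Unweighted score  0.0  58.12  0.00393 0.136         93.5       6.5
#> 2  initial All variants (2SLS)  0.0   3.26  0.14430 0.109         74.0      26.0
#> 3  initial All variants (LIML)  0.0   3.26 -0.01031 0.172         93.5       6.5
#> 4  initial    Unweighted score  0.2  57.82  0.21813 0.169         97.5      35.5
#> 5  initial All variants (2SLS)  0.2   3.29  0.34603 0.128         67.0      88.5
#> 6  initial All variants (LIML)  0.2   3.29  0.21492 0.216         94.5      41.0
```

Under the null the score's median estimate is 0.004 with ~95% coverage;
2SLS is centred at 0.14 (towards the confounded 0.49) and covers only 74%
of the time. LIML is median-unbiased but its default standard errors
under-cover slightly. A command-line front end wrapping the same functions
lives at `inst/cli/allelescore.R` (subcommands `simulate`, `score`,
`estimate`, `study`).

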