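---
title: "Allele scores as instruments: model, calibration and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele scores as instruments: model, calibration and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelescore)
```

## The generating model

Each simulated individual $i$ carries $J$ independent biallelic variants in
Hardy–Weinberg equilibrium: dosage $G_{ij} \sim \mathrm{Binomial}(2, p_j)$
counts minor alleles at minor allele frequency $p_j$. The risk factor and
outcome are

$$
X_i = \sum_j \delta_j \alpha_j G_{ij}
    + \sum_j \gamma_j 1[G_{ij} = 1]
    + \sum_{j<k} \delta_{jk} G_{ij} G_{ik}
    + \sum_j \kappa_j G_{ij} V_i + \theta_V V_i
    + c_X U_i + \epsilon_{Xi},
$$
$$
Y_i = \beta_X X_i + c_Y U_i + \epsilon_{Yi},
$$

with $U_i, V_i \sim N(0,1)$ latent (an unmeasured confounder and a
non-confounding covariate) and independent normal errors. Every term other
than the additive $\alpha_j$ sum is zero except under the scenario that
studies it. Under the `invalid` scenario a variant with validity indicator
$\delta_j = 0$ moves its term into the confounder,
$U_i \mathrel{+}= \sum_j (1-\delta_j)\alpha_j G_{ij}$, so an invalid variant
is associated with $U$ exactly as strongly as a valid one is with $X$ — the
violation is empirically invisible.

Structural assumptions inherited by all estimators: linearity of both
equations, homogeneous effects, independent variants (no linkage
disequilibrium), continuous traits.

## Parameter calibration

Several scales must be fixed jointly; the package's defaults are calibrated
so that a handful of analytically computable diagnostics take realistic
values, and they are the conditions under which all reported summaries are
computed.

| parameter | default | units / role |
|---|---|---|
| $n$ | 3000 | individuals per dataset |
| $J$ | 25 (9, 100 supported) | variants |
| $p_j$ | 0.3 | minor allele frequency |
| $\alpha_j$ | $0.3/\sqrt{J}$ = 0.06 at $J{=}25$ | risk-factor units per allele |
| $c_X, c_Y$ | 1 | confounder loadings |
| $\mathrm{sd}(\epsilon_X), \mathrm{sd}(\epsilon_Y)$ | 1 | error scales |
| $\beta_X$ | 0; studies cycle 0, 0.2, 0.4 | causal effect |
| replicates | 1000 | per study cell |

With these values the variance of a dosage column is $2pq = 0.42$, the
genetic variance of $X$ is $J\alpha^2 \cdot 2pq = 0.0378$, and
$\mathrm{var}(X) = 0.0378 + 1 + 1 \approx 2.04$. Three consequences pin the
calibration down:

* the adjusted $R^2$ of $X$ on the variants is
  $0.0378 / 2.04 \approx 1.9\%$ — a typical variance-explained for a
  biomarker score;
* the expected first-stage F of the score,
  $\approx (R^2/(1-R^2))\,(n-2) \approx 58$, is comfortably strong, while
  per-variant F is $\approx 3.3$ — firmly in weak-instrument territory for
  the multivariable estimators;
* the confounded observational slope under the null is
  $c_Xc_Y/\mathrm{var}(X) \approx 0.49$, giving a visible target towards
  which biased estimators drift.

Scaling $\alpha$ as $0.3/\sqrt{J}$ holds all three quantities fixed across
$J \in \{9, 25, 100\}$, so comparisons across instrument counts change only
the number of first-stage parameters, not instrument strength.

### Scenario-specific choices

* **Unequal effects**: $\alpha_j \sim N(0.06, 0.018^2)$ — a 30% coefficient
  of variation keeps nearly all effects in $(0.02, 0.12)$, unequal but all
  risk-increasing.
* **Major-gene/polygene**: two main variants at five times the secondary
  effect. Only the ratio is fixed a priori; the magnitudes are solved from
  the constraint that the *unweighted score's* variance explained stays at
  the equal-effects level, i.e. $\sum_j \alpha_j = J\bar\alpha$
  ($\alpha_s = 1.5/33 \approx 0.045$, $\alpha_m \approx 0.227$ at
  $J = 25$). The alternative normalization — holding the *total genetic
  variance* constant — was rejected because it makes the weighted-score and
  composite instruments as weak as in the equal-effects design, defeating
  the purpose of the scenario: the interesting regime is precisely that
  true weights concentrate strength ($F \approx 95$ for the true-weight
  score, $\approx 32$ for the three-instrument composite) while the
  unweighted score is unchanged.
* **Non-linear effects**: heterozygote deviations
  $\gamma_j \sim N(0, 0.036^2)$; $\gamma_j = -\alpha_j$ is a recessive
  coding and $\gamma_j = +\alpha_j$ a dominant one, so the draw spans
  realistic departures from additivity.
* **Variant–variant interactions**: each of the $J(J-1)/2$ pairs interacts
  with probability 0.1, coefficient $N(0, 0.036^2)$ — about 30 active pairs
  among 300 at $J = 25$; interactions use raw dosage products.
* **Variant–covariate interactions**: each variant interacts with $V$ with
  probability 0.5, coefficient $N(0, 0.036^2)$; $V \sim N(0,1)$ with main
  effect $\theta_V = 1$. The extra covariate variance dilutes the score's
  first-stage F to roughly 39; since no diagnostic pins $\theta_V$ down
  analytically, 1 (the confounder's scale) is the natural choice and the
  score's robustness conclusions do not depend on it.
* **Invalid instruments**: validity $\delta_j \sim \mathrm{Bernoulli}(p)$,
  $p \in \{0.9, 0.7, 0.5\}$. A useful closed form: under the null, the
  score IV estimand with invalid fraction $f$ is
  $f c_Y / ((1-f) + f c_X) = f$ at unit loadings. The bias therefore scales
  one-for-one with the invalid fraction (0.10, 0.30, 0.50), and at $f = 1$
  the estimand is the confounder-pathway ratio $c_Y/c_X = 1$ — not the
  observational slope, which it only happens to approximate near $f = 0.5$.

Randomized architecture components (effect sizes, interaction coefficients,
validity flags) are redrawn for every replicate, so summaries average over
architectures as well as samples; `run_cell(redraw_architecture = FALSE)`
fixes a single draw instead. Medians are essentially unaffected by the
choice; between-replicate spread is slightly larger when redrawing.

## Scores and weighting procedures

The unweighted score is the allele count $\sum_j G_{ij}$. Weighted variants
differ only in where $w_j$ comes from:

* **internal** — the coefficients of the *joint* multivariable first-stage
  regression of $X$ on all variants. This makes the weighted-score IV
  estimate identical (to numerical precision) to multivariable 2SLS, which
  is exactly why the procedure is dangerous: it inherits 2SLS's
  weak-instrument bias while appearing to use a single strong instrument.
  The package deliberately uses the joint regression, not per-variant
  marginal slopes, so this identity holds and is tested.
* **cross-validated** — individuals are split at random into $k$ folds
  (no stratification; remainders spread one per fold); each fold is scored
  with weights fitted on its complement. The correlation between weights
  and the scored data is removed by construction, at the cost of weights
  estimated on $(k-1)/k$ of the sample.
* **external** — true weights perturbed by $N(0, \mathrm{sd}^2)$ noise;
  sd = 0.04 emulates an external study of about the analysis sample's size,
  sd = 0.01 one sixteen times larger. Perturbed weights may be negative; no
  truncation is applied, matching how estimated external weights behave.
* **true** — the generating $\alpha_j$, the efficiency benchmark. With
  equal effects it is proportional to the unweighted score, so the two give
  identical estimates.

Data-driven selection ranks variants by the univariate F statistic of $X$
on each variant (equivalently squared t; the ordering matches the P-value
ordering), ties broken by variant index, then keeps the top $k$ or those
with $P$ below a threshold, scoring the selected set unweighted. Selection
and estimation on the same data produce winner's-curse bias — the point of
including the procedure. A threshold that selects nothing makes that
replicate non-estimable; such replicates are dropped from summaries and
counted in `n_reps_used` rather than imputed.

## Estimators and numerical conventions

All IV estimators work on intercept-partialled (demeaned) data through a QR
decomposition of the instrument matrix; rank deficiency raises a
singular-design error rather than silently dropping columns.

* **2SLS**: $\hat\beta = (x'P_Zx)^{-1}x'P_Zy$; SE from second-stage
  residuals computed with the observed $x$, homoskedastic,
  $\hat\sigma^2 = \mathrm{RSS}/(n-2)$.
* **LIML**: the k-class estimator at $k = \lambda_{\min}$, the smallest
  root of $\det(W'M_1W - \lambda W'M_ZW) = 0$ with $W = [y, x]$. Because
  $W$ has two columns this is a quadratic with closed-form roots — no
  iterative eigensolver, no convergence tolerance beyond a guard on the
  discriminant ($> -10^{-8}$ relative) against degenerate cross-product
  matrices. $\lambda_{\min} \ge 1$ when overidentified and $= 1$
  just-identified, where LIML, 2SLS and the ratio estimator coincide.
  Standard errors are the default (non-Bekker) k-class asymptotic SEs;
  the Bekker correction is out of scope, and the under-coverage of default
  LIML intervals at large $J$ is part of what the studies quantify.
* **Composite**: 2SLS on each main variant plus the unweighted score of the
  secondary variants — three instruments in the two-main-variant design;
  degenerate with zero main variants to the plain score IV.
* **Confidence intervals** are Wald, $\hat\beta \pm 1.96\,\mathrm{SE}$
  (normal, not t, critical values; at $n = 3000$ the difference is below
  $10^{-3}$ on the interval width and invisible at Monte Carlo precision).
* **Degenerate first stages** ($x'P_Zx$ at rounding-error scale) are
  reported as non-estimable rather than returning an effectively infinite
  estimate.

## Study summaries

Each study cell reports the mean first-stage F, the median estimate and its
IQR (medians because the estimate distributions are heavy-tailed; under
weak instruments the mean need not exist), empirical coverage of the 95%
intervals, and power against $\beta = 0$ at two-sided 5%. Quartiles use
linear interpolation (quantile type 7, the dominant convention; differences
between types are far below Monte Carlo error at 1000 replicates).
$|z| = 1.96$ exactly counts as rejection — a measure-zero boundary. Monte
Carlo SEs accompany each cell: $\sqrt{p(1-p)/R} \times 100$ for coverage
(0.69 points at $R = 1000$, $p = 0.95$) and the asymptotic density formula
$1.2533\,\hat\sigma/\sqrt{R}$ with $\hat\sigma = \mathrm{IQR}/1.349$ for
the median.

Reproducibility: each replicate's seed is a deterministic 31-bit hash of
the master seed and the cell's *data-generating* coordinates (scenario,
$\beta_X$, $n$, $J$, validity probability, replicate index) — not the
analysis method. Methods compared within a cell therefore consume
bit-identical datasets (a paired design, verified by dataset checksums),
any single replicate can be regenerated in isolation, and a JSON manifest
(`write_manifest()` / `run_table_from_manifest()`) reproduces a full table
bit-for-bit, with doubles serialized at 17 significant digits so they
round-trip exactly.

## What the generator does and does not emulate

It emulates: polygenic additive architectures with realistic
variance-explained; confounding strong enough to matter (observational
slope 0.49 under the null); weak instruments at exactly the strength where
2SLS fails and a score does not; misspecified genetic models; pleiotropy
through a confounder. It does **not** emulate: linkage disequilibrium or
correlated variants, population stratification, binary outcomes or
case-control ascertainment, missing genotypes, or effect heterogeneity
across individuals. Conclusions from passing tests are therefore about
estimator behaviour under the modelled mechanisms, not about robustness to
correlated instruments or non-collapsibility — both known to raise separate
issues in practice.

## Problem sizes used by the test suite

Unit and property tests run at small scale ($n$ from 60 to a few thousand,
$J \le 10$, tens of replicates) with independently coded oracles: normal
equations via `solve()`, covariance ratios, explicit residual-maker
matrices with `eigen()` for $\lambda_{\min}$, full-sort quantiles, and
brute-force enumeration of the dosage distribution. The reproduction tests
run the reference design itself — 1000 replicates of $n = 3000$ at
$J = 25$ (one cell at $J = 100$) — matching the scale at which the headline
summaries are defined; the same cells are recomputed from scratch by
`scripts/acceptance.R`. One reproduction check is fragile by construction:
at 50% validity the reference median (0.49) differs from the theoretical
estimand (0.50) by about one Monte Carlo standard error, so a ±0.015 band
around it is met only for favourable seeds; the package reports whatever
the seed produces rather than tuning towards the reference value.

## Known limitations

* LIML standard errors are the software-default k-class SEs; with many
  instruments their under-coverage is reported, not corrected (no Bekker
  adjustment, no Fuller modification).
* Jackknife (leave-one-out) weighting is not implemented; cross-validation
  tops out at user-chosen $k$.
* The CLI ingests delimited dosage tables only — no VCF/PLINK readers.
* Reorienting alleles on the analysis sample (`reorient_genotypes()`) is
  itself a data-driven choice; the function warns accordingly.
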