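---
title: "Methods: a hierarchical hurdle model for workplace air monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical hurdle model for workplace air monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airhurdle)
```

## The problem

Compliance air-monitoring programs produce large collections of workplace
air samples: a substance, a workplace (classified by a two-level industry
code), and a measured concentration — very often zero, because the analyte
was not found above an unknown detection limit. `airhurdle` models such
data with a two-stage ("hurdle") structure so that the prevalence of
nondetects and the magnitude of detected concentrations are described by
separate, jointly usable models, and uses the result to screen
substance-by-workplace pairs for potential inhalation exposure.

## Model

Let $i$ index inspection-level observations, $j[i]$ the workplace
subsector, and $x_{im}$ the standardized physicochemical descriptors of the
sampled substance together with all pairwise products ($P$ main effects
plus $P(P-1)/2$ interactions). Both stages share the linear predictor

$$\eta_i = \beta_{1j[i]} + \sum_m \beta_{2m} x_{im}.$$

- **Detection stage** (all observations): $y_i \in \{0,1\}$,
  $y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\eta_i))$.
- **Concentration stage** (detected observations only): the base-10
  logarithm of the concentration in mg m$^{-3}$,
  $y_i \sim \mathrm{Normal}(\eta_i, \sigma_\varepsilon)$.

The subsector intercepts are partially pooled through the industry
hierarchy: $\beta_{1j} \sim T_\nu(s_{k(j)}, \sigma_0)$ around their sector
mean, and $s_k \sim T_\nu(\mu, \sigma_{01})$ around a global location.
Sparse subsectors therefore borrow strength from their sector — a
subsector observed twice is pulled toward its sector mean rather than its
noisy empirical estimate — while heavy Student-T tails let genuinely
unusual subsectors escape the pooling.

Priors are the standard weakly informative choices for hierarchical GLMs
on standardized predictors: $\beta_{2m} \sim T_3(0, 2.5)$,
$\mu \sim N(0, 5)$ on the logit stage and $N(0, 10)$ on the concentration
stage, and half-Cauchy(2.5) on every scale
($\sigma_0, \sigma_{01}, \sigma_\varepsilon$). $\nu$ is fixed at 3 by
default (heavy-tailed but proper) and exposed in `model_config()`.

## Inference

`fit_stage()` treats the inference backend as a contract: any method that
returns joint posterior draws of all parameters is admissible, and the
package validates its backends by parameter-recovery and calibration
simulations rather than by fiat.

- **`method = "laplace"`** (default): a full-rank Gaussian approximation
  centred at the posterior mode. The mode is found by BFGS on the exact
  joint log posterior with analytic gradients (scales optimized on the log
  scale with the Jacobian included); the covariance is the inverse Hessian
  at the mode, computed by finite differences of the analytic gradient and
  floored at a relative eigenvalue of $10^{-10}$ for numerical
  definiteness. Draws are exact samples from that Gaussian; scale
  parameters are exponentiated back, which also makes their marginal
  summaries asymmetric as expected. The method is deterministic given the
  seed and fits the default study (about 27,000 training observations, 62
  parameters per stage) in seconds.
- **`method = "mcmc"`**: the same model expressed in JAGS, used as the
  reference method. The test suite checks that the two backends agree on
  coefficient posterior means (within 0.1 on a small instance) and that
  with no data the MCMC posterior reproduces the prior quantiles.

The Gaussian approximation is exact in neither tail; with the data sizes
this package targets, coefficient posteriors are effectively Gaussian and
replicated simulations in the test suite show near-nominal interval
coverage. For small datasets prefer `method = "mcmc"`.

## Preprocessing rules

`preprocess_samples()` reproduces the standard cleaning sequence for
compliance air data, logging every dropped row:

1. **Sample types.** Only `personal` and `area` samples are kept, treated
   identically; blanks, wipes, bulk and other samples are removed.
2. **Units.** Everything is converted to log10 mg m$^{-3}$. ppm uses
   $\mathrm{mg\,m^{-3}} = \mathrm{ppm} \times MW / 24.45$ (molar volume
   24.45 L mol$^{-1}$ at 25&nbsp;°C and 1 atm, the industrial-hygiene
   convention); percent is $10^4$ ppm; mass-only results are divided by
   the sampled air volume. A reported value of zero is a nondetect.
   Fibers/cc, ppm or percent without a molecular weight, and mass without
   an air volume cannot be converted and are dropped.
3. **Industry codes.** A user-supplied concordance maps legacy codes to
   the current two-level classification; rows matching zero or multiple
   (sector, subsector) pairs are dropped.
4. **Aggregation.** Samples collapse to one observation per
   (inspection, substance), keeping the *maximum* converted value — a
   deliberate worst-case-exposure convention. The group key includes the
   substance because one inspection can sample several analytes.
5. **Outliers.** Within each substance, detected values with $|z| > 4$
   (inclusive mean and sample sd over that substance's detects) are
   removed. Substances with fewer than three detects or zero spread are
   exempt; with an inclusive sd, $|z| \le (n-1)/\sqrt{n}$, so tiny groups
   could never be flagged anyway.
6. **Sparse subsectors.** Subsectors with fewer than 10 detects lose all
   their rows (detects and nondetects); their intercepts would otherwise
   be pure prior.
7. **Substances without descriptors** (outside the QSAR domain) are
   dropped when a property table is supplied.

The train/test split is *by substance* (default 10% of substances held
out), so test performance reflects property combinations the model never
saw.

## Design matrix

Descriptor sets from QSAR pipelines are frequently collinear.
`prune_correlated()` links properties with $|r| > 0.85$ into connected
groups and keeps one per group according to an explicit priority order —
which member to keep is a judgment call, so it is configuration, not
inference. Retained properties are centred and scaled *on the training
substances only* and the same parameters are re-applied to test or
screening substances. Interactions are products of the standardized mains
and are not re-standardized, the common convention for hierarchical GLMs;
this keeps interaction coefficients interpretable against the
$T_3(0, 2.5)$ prior.

## Prediction and screening

For a (substance, subsector) query, `predict_detection()` returns
per-draw detection probabilities and `predict_concentration()` per-draw
conditional log10 concentrations, with or without residual noise: with
residual noise the draws are posterior predictive (what a new observation
would look like); without, they represent the conditional mean. Interval
summaries are equal-tailed quantiles; screening output reports the median
back-transformed to mg m$^{-3}$ as well. Workplace types outside the
fitted hierarchy are refused by default; an explicit `novel = TRUE` flag
instead zeroes the subsector intercept so the prediction uses the fixed
effects alone — the package deliberately does not extrapolate silently.

## Evaluation and the null baseline

`evaluation_report()` computes the confusion matrix at threshold 0.5 on
the posterior median detection probability (an error of exactly the
threshold counts as a detect), AUC as the Mann–Whitney pair statistic with
0.5 credit for ties, RMSE on true positives, the fraction of true
positives within one order of magnitude (boundary inclusive), and a
combined hurdle accuracy: a case succeeds if detection status is predicted
correctly and, for detects, the concentration is within one order of
magnitude. Every metric is reported side by side with a null baseline
that knows only the training detection rate and the training mean detected
concentration. Because a constant-rate null can be classified either
deterministically (threshold) or by sampling flags at the base rate —
published baselines are sometimes one, sometimes the other — `null_flags()`
provides both; the deterministic variant is the default.

## The synthetic study

The package is validated end to end on synthetic data with known ground
truth, because real compliance datasets have no ground truth to recover.
`default_run_config()` defines the study: 8 sectors, 30 subsectors, 300
substances with 6 descriptors (21 predictors), 30,000 observations,
roughly 40–50% nondetects, detected concentrations spanning several orders
of magnitude, and a residual sd of 1.0 log10 mg m$^{-3}$ — sizes chosen to
emulate the structure of public compliance air data at a scale that fits
in minutes on a single core. Raw records are expanded from clean
observations with a shifted-geometric samples-per-inspection count
(median 3), invertible unit re-expression (ppm, percent, mass + volume)
and injected junk (blanks, wipes, inconvertible units, unmappable and
ambiguous codes, extreme outliers), each category recorded in a ledger so
the preprocessing pipeline's drop log can be audited row for row.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes: detection-limit censoring
(real nondetects are left-censored at unknown, time-varying limits; the
generator's detection stage is a clean Bernoulli process), temporal
trends, inspection-targeting bias, correlated repeat visits to the same
workplace, and real industry code strings. Two further honest
consequences of the heavy-tailed generative process: a clean synthetic
table can itself contain rows that the $|z| > 4$ rule legitimately
removes, and injected outliers can only be detected in substance groups
of at least ~19 observations (the inclusive-sd bound), which the injector
respects.

## Numerical choices and degenerate inputs

- BFGS initialization: global location at the empirical logit (clamped to
  [0.02, 0.98]) or mean response; hierarchy levels start at that location;
  scales at 0.5 (residual sd at the response sd).
- Quantile summaries use R's default type-7 quantiles; ranking ties break
  by substance id so results are permutation-invariant.
- Zero scales in the generator (`sigma0 = 0`, `coef_sd = 0`) are allowed
  and collapse the corresponding level exactly, which the degenerate-limit
  tests exploit.
- Draw matrices round-trip through disk bit-identically: they are written
  as columnar CSV with `%.17g` formatting, which preserves IEEE doubles
  exactly.
- Stage seeds are derived from one global seed by hashing the stage name,
  so `run_pipeline()` output is reproducible as a whole and per stage.

## Limitations

The model predicts the *distribution* of concentrations given detection at
the worst-case (per-inspection maximum) aggregation level; it is a
screening tool, not an exposure reconstruction. Its industry resolution
stops at the subsector: within-subsector heterogeneity (room size,
ventilation, task) is absorbed into $\sigma_\varepsilon$. The Laplace
backend understates tail asymmetry of scale parameters in small samples.
And because properties enter linearly (plus pairwise products), strongly
nonlinear structure–exposure relationships are out of scope.
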