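---
title: "Probabilistic imputation for risk calculators with systematically missing inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic imputation for risk calculators with systematically missing inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical risk calculators need inputs that are not always available. The
SCORE2 model estimates a 10-year probability of fatal or non-fatal
cardiovascular disease from age, smoking status, systolic blood pressure
(SBP), total cholesterol (TotalC), HDL cholesterol (HDLC) and diabetes
status — but the three clinical variables require a blood draw or a
measurement visit and can be *systematically* missing in a population of
interest (missing for every patient, by design, rather than occasionally).
`riskimpute` treats the calculator as a black box and asks: given the
variables a patient does know — age, smoking status, diabetes status and
optionally BMI — what can we say about their risk?

Five methods map a patient plus a training cohort to a *risk forecast*, an
empirical distribution over risk values (a single atom, i.e. a Dirac
distribution, for the point methods):

* **I1 — mean patching.** Replace each missing input by its training-cohort
  sample mean, evaluate once.
* **I2 / I5 — MICE.** Append the patient to the cohort, run multiple
  imputation by chained equations with predictive mean matching, evaluate
  the calculator on the patient's row of each of the $m$ completions. I5
  keeps the full empirical distribution of the $m$ risks; I2 is its mean as
  a point prediction.
* **I3 / I4 — Gaussian copula.** Fit marginal distributions to each
  continuous covariate, transform to standard-normal margins
  ($z = \Phi^{-1}(\hat F(x))$), estimate a correlation matrix, and condition
  the unknown block on the patient's known values by multivariate-normal
  conditioning:
  $\mu_{1|2} = \Sigma_{12}\Sigma_{22}^{-1}z_{\text{known}}$,
  $\Sigma_{1|2} = \Sigma_{11} - \Sigma_{12}\Sigma_{22}^{-1}\Sigma_{21}$.
  Conditional draws are back-transformed through the marginal quantile
  functions. I3 plugs in the conditional means; I4 propagates the full
  conditional distribution through the calculator ($n$ Monte Carlo draws,
  default 500).

## The risk engine

The SCORE2 model is a log-subdistribution-hazard linear predictor on
centered covariates (age centered at 60 per 5 years; SBP at 120 mmHg per
20 mmHg; TotalC at 6 mmol/L; HDLC at 1.3 mmol/L per 0.5 mmol/L), with
age-interaction terms, a 10-year baseline survival $S_0$, and a region/sex
recalibration on the cloglog scale:

$$\text{risk} = 1 - \exp\!\big(-\exp(s_1 + s_2\,
  \ln(-\ln(1 - (1 - S_0^{\exp(\beta^\top x)})))\big).$$

The published coefficient table is embedded as a plain-text file
(`inst/extdata/score2_coefficients.txt`) keyed by sex and region, so male
support and other regions are data additions, not code changes. The default
is a female patient in the low-risk region (Switzerland). Diabetics are
outside SCORE2's target population: the flag is accepted, the published
coefficients are applied, and a warning is emitted. Ages outside 40–69 warn
but evaluate.

Risk categories use strict cuts: low iff risk $< 1\%$, high iff
risk $> 5\%$, boundaries fall in the middle band.

## Scoring

Point and probabilistic forecasts are compared on one scale by treating
point predictions as Dirac distributions and using proper scoring rules:

* **CRPS**: $\int (\hat F(x) - \mathbf 1\{x \ge y\})^2\,dx$, computed
  exactly for the step-function empirical CDF by summing over breakpoints.
  For a Dirac it reduces to the absolute error. An independent energy-form
  identity ($\mathbb E|X-y| - \tfrac12\mathbb E|X-X'|$) is used as a
  cross-check in the tests (agreement to $10^{-10}$).
* **Threshold Brier scores**: squared error between the forecast
  probability of an event and its indicator. The events are "risk below 1%"
  (probability $\hat F(0.01)$, outcome $\mathbf 1\{y < 0.01\}$) and "risk
  above 5%" (probability $1 - \hat F(0.05)$, outcome
  $\mathbf 1\{y > 0.05\}$). We adopt the indicator convention
  $y = \mathbf 1\{\text{condition holds}\}$ for both thresholds, which
  makes both formulas proper squared errors; the alternative 0-coding found
  in some presentations is internally inconsistent and is not used.

Classification thresholds the forecast event probability at a cut-off
$\alpha$; sweeping $\alpha$ over the observed probabilities gives exact ROC
curves with trapezoidal AUC (no grid artifacts).

## The synthetic cohort

The study population this package emulates is a cohort of 359 women aged
40–69 from a menopause clinic, which is not publicly deposited. The
generator reproduces its published *marginal* structure:

| variable | family | parameters |
|---|---|---|
| age (years) | Normal | (50.82, 5.88) |
| BMI (kg/m²) | log-Normal | (3.22, 0.19) |
| TotalC (mmol/L) | Gamma | shape 31.48, scale 0.17 |
| HDLC (mmol/L) | log-Normal | (0.54, 0.30) |
| SBP (mmHg) | Gamma | shape 59.86, scale 2.07 |

with smoking prevalence 74/359 and no diabetics. Gamma distributions are
(shape, scale) **everywhere**; the (shape, rate) convention would give a
blood pressure mean of ~29 mmHg instead of ~124. Two small reference
discrepancies are worth knowing: the descriptive age standard deviation is
printed as 5.67 while the fitted Normal parameter is 5.88 (we use the
fitted 5.88), and the rounded TotalC/BMI parameters imply analytic means
about 0.5% away from the printed descriptive means (hence the 1.5%
tolerance on those two in the tests).

The cohort's *dependence* structure is unpublished. `default_corr()`
therefore encodes a stated invention: a positive-definite matrix whose sign
pattern follows established epidemiology (TotalC and SBP rise with BMI and
age, HDLC falls with BMI) with moderate magnitudes (0.05–0.35). Results on
synthetic cohorts are claims about this generator, not about the study
data: passing benchmarks show the machinery ranks methods correctly *when
the generator's dependence assumptions hold*. Real data additionally
exhibit features the generator omits by design: rounding of blood-pressure
readings, heavier-than-lognormal HDLC tails, and any smoking–covariate
dependence (smoking is generated independently; a custom correlation
matrix hook is the escape hatch).

Age truncation to [40, 69] is by whole-row resampling, which preserves the
joint shape inside the window; clipping would create boundary atoms.

## Numerical choices

* **Copula fitting.** Marginal CDF values are clamped to
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 1/(4n)$, before
  $\Phi^{-1}$; the correlation matrix is the Pearson correlation of the
  z-scores, repaired to positive semi-definiteness by eigenvalue clipping
  when needed. A singular known-block in conditioning falls back to a
  ridge-regularized inverse ($\lambda = 10^{-8}$).
* **Conditional means on the original scale.** I3's plug-in values are
  Monte Carlo averages of back-transformed draws, not back-transforms of
  Gaussian-scale means — the two differ for skewed marginals, and the
  quantity of interest is the mean of the covariate itself.
* **MICE.** Defaults: $m = 500$ imputations (matching I4's 500 draws, so
  the two probabilistic forecasts have equal resolution), 10 FCS sweeps
  with a per-iteration trace in place of a formal convergence test, donor
  pool 5, predictors age + BMI. The regression step draws residual variance
  from its scaled inverse-$\chi^2$ posterior and coefficients from their
  conditional normal; donor distance is the absolute difference of
  predicted means, ties broken by a seeded shuffle. Rank-deficient designs
  fall back to a small ridge. When the rows observed on a target are
  complete on its predictors (the typical one-patient-appended case), the
  least-squares decomposition is computed once and reused across chains —
  an algebraic identity, not an approximation.
* **Seeds.** One root seed; every stochastic step (patient, method, chain)
  derives a 31-bit substream seed from it, so leave-one-out results are
  independent of evaluation order and bitwise reproducible.

## Benchmarks and problem sizes

`loo_benchmark()` masks each scenario's variables for one patient at a
time, refits all training-side models on the remaining rows, forecasts, and
scores against the patient's true calculated risk. The shipped tests
exercise the full study-size cohort ($n = 359$) under the
all-clinical-missing scenario with reduced Monte Carlo sizes
($n_{\text{mc}} = m = 100$, 5 FCS sweeps) — the quantity under test is the
*ordering* of the methods (the probabilistic I4/I5 beat the point methods
I1–I3 in mean CRPS, and BMI improves I4), which is insensitive to the
forecast resolution; study-scale runs use 500/500/10. The sample-size study
shares its benchmark seed across repeats so that the spread across repeats
isolates subsampling variability.

One design question is where the test patient enters the MICE run; we
append the patient (with missing cells) to the training cohort, the
arrangement under which the imputation model is fitted to exactly the data
a practitioner would have. Another is the choice of $m$: a cross-validated
selection is possible in principle, but no selection criterion is obviously
canonical, so $m$ is an explicit configuration knob instead.

## Limitations

* The Gaussian copula is an assumption of convenience; strictly increasing
  marginal transforms cannot make a non-Gaussian dependence Gaussian. Vine
  or mixture copulas are out of scope here.
* Headline scores depend on the unpublished cohort; only ordering and
  monotonicity properties are asserted on synthetic data.
* The embedded coefficients reproduce every non-smoker worked evaluation we
  validate against exactly; one published smoker example does not reconcile
  with the published female low-risk coefficient set and is tracked in the
  test suite as an expected divergence rather than a failure.
* Categorical imputation (logistic/polytomous) and Rubin's rules for
  parameter pooling are out of scope: uncertainty is propagated to the
  predicted risk, not to model parameters.
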