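---
title: "Vancomycin population PK/PD in pediatric patients: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vancomycin population PK/PD in pediatric patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vancoped)
```

## The model

Vancomycin disposition is described by a one-compartment model with
zero-order (infusion) input and first-order elimination. Under repeated
intermittent infusion every quantity of interest has a closed form, which
keeps the likelihood, the MAP objectives and the Monte Carlo layers fast
and free of ODE-solver error: the concentration at any time is the
superposition of per-dose infusion segments, the steady-state peak and
trough are geometric-series limits, and the daily steady-state exposure is
AUC~0–24~ = daily dose / CL (linear PK).

Between-patient differences enter through a covariate submodel on the two
structural parameters,

$$CL = \theta_1\,(CLCr/90.28)^{\theta_3}\,(WT/58.25)^{\theta_4}\,e^{\eta_{CL}},
\qquad
V = \theta_2\,(AGE/55)^{\theta_5}\,(WT/58.25)^{\theta_6}\,e^{\eta_V},$$

normalized so that $\theta_1$ and $\theta_2$ are the typical values of a
reference adult (creatinine clearance 90.28 mL/min, weight 58.25 kg, age
55 years). The unified adult/pediatric form — renal function *and* body
weight on clearance, age and weight on volume — is what allows a single
parameter set to extrapolate across the whole age range, provided the
covariates themselves carry the maturation signal.

Random effects $\eta = (\eta_{CL}, \eta_V)$ are normal with diagonal
covariance; the reported $\omega^2$ values are variances (so the
approximate CV of clearance is $\sqrt{0.204} \approx 45\%$). The residual
error is proportional, $y = f\,(1+\varepsilon)$,
$\varepsilon \sim N(0, \sigma^2)$: $\sigma^2 = 0.0749$ implies a ~27%
assay-plus-model CV, which is the right order for immunoassay TDM, whereas
an *additive* variance of 0.0749 mg²/L² would be implausibly small.
Whether the original analysis used a proportional, additive or combined
form is not documented; the proportional reading is this package's choice
and is carried consistently through simulation, estimation and
diagnostics.

### Default parameter values

| symbol | meaning | default | units |
|---|---|---|---|
| $\theta_1$ | typical CL | 3.83 | L/h |
| $\theta_2$ | typical V | 44.7 | L |
| $\theta_3$ | CLCr exponent on CL | 0.516 | – |
| $\theta_4$ | weight exponent on CL | 0.646 | – |
| $\theta_5$ | age exponent on V | 0.33 | – |
| $\theta_6$ | weight exponent on V | 0.349 | – |
| $\omega^2_{CL}$ | IIV variance of CL | 0.204 | – |
| $\omega^2_{V}$ | IIV variance of V | 0.0427 | – |
| $\sigma^2$ | proportional residual variance | 0.0749 | – |

`dosing_regimen()` defaults the infusion duration to 1 h (standard
vancomycin practice; configurable), and age is decimal years with neonates
on postnatal age (> 0; an age of exactly zero is rejected because the
power term would collapse).

## Creatinine clearance in children

The covariate model needs CLCr, which routine pediatric data rarely
report directly. `creatinine_clearance()` fills it: Cockcroft–Gault for
patients 18 years and older, and the bedside Schwartz estimate
$0.413 \cdot \text{height(cm)} / S_{Cr}(\text{mg/dL})$ below 18 (serum
creatinine converted from µmol/L by 1/88.42).

The open design question is the *scale* of the pediatric value: bedside
Schwartz is indexed to 1.73 m² body surface area, while Cockcroft–Gault is
absolute. This package feeds the **normalized** Schwartz value directly
into the covariate equation, for two reasons grounded in the observable
consequences of the choice:

* **Exposure level.** With the normalized scale, a typical infant
  (0.46 y, 5.4 kg, SCr 20 µmol/L) has CL ≈ 1 L/h, so 40–60 mg/kg/day
  yields AUC~0–24~ around 220–330 mg·h/L — the range actually observed
  in pediatric TDM cohorts at those doses. The absolute scale
  (BSA/1.73-scaled, ≈ 19 mL/min for that infant) would put AUC near 600
  at the same dose, inconsistent with those exposures.
* **Age ordering.** With the normalized scale, weight-normalized
  attainment improves with age (adolescents reach a given AUC/MIC target
  at a lower mg/kg dose than infants), the clinically established
  pattern; the absolute scale reverses this ordering.

`creatinine_clearance(..., scale = "absolute")` provides the alternative
for sensitivity analyses. Supplied CLCr values always pass through
untouched.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` produces
virtual cohorts whose *statistical structure* matches a
neonate-and-infant-dominated pediatric TDM study:

* **Age** is log-uniform within the band. For the mixed band
  (0.0164–13 y) the implied median is
  $\sqrt{0.0164 \cdot 13} \approx 0.46$ y, reproducing a cohort in which
  most patients are under 3 years.
* **Weight and height** follow compact piecewise-linear median-for-age
  tables (birth 3.3 kg / 0.50 m through 17 y 55 kg / 1.65 m) with
  log-normal scatter (CV 15% and 4%), truncated to 0.9–55 kg and
  0.30–1.70 m. The knot tables are arguments, so a full growth-chart
  reference can be swapped in without touching the code.
* **Serum creatinine** is normal with mean $18 + 2\,\text{age}$ µmol/L and
  SD 6, truncated to 9–83 µmol/L.

`simulate_tdm()` reproduces the routine-care sampling design: doses
through the fifth administration, one trough 0.5 h before the fifth dose,
one peak drawn uniformly 0.5–1 h after the end of that dose's infusion
(the design fields are configurable), proportional observation noise, and
BLQ flagging below the assay's lower limit of quantification
(3.00 mg/L). `simulate_outcomes()` adds Bernoulli clinical/microbiological
outcomes at configured marginal rates (defaults: 92.6% improvement), an
optional log-odds slope on log₂(AUC/MIC) for power studies, and isolate
MICs on the doubling-dilution grid.

What the generator does **not** emulate: time-varying renal function,
adherence and dosing-history irregularities, growth-chart fidelity beyond
the piecewise medians, inter-occasion variability, and any correlation
between covariates and outcomes beyond the configured exposure–response
slope. Passing tests therefore demonstrate that the estimators and
simulators are correct *under the stated model*, not that the model
captures every feature of real pediatric data.

### BLQ policy

Concentrations below 3.00 mg/L are flagged at parse/simulation time but
never dropped from the dataset. Fitting and MAP estimation exclude them
from the likelihood by default (the M1 strategy); `include_blq = TRUE`
imputes LLOQ/2 = 1.50 mg/L instead, the value that summary medians of
heavily censored troughs gravitate to. The policy is applied downstream so
that one dataset supports both choices.

## Estimation

`fit_popk()` minimizes a FOCE-type marginal objective. For each subject
the conditional objective

$$g_i(\eta) = \sum_j\left[\frac{(y_j-f_j(\eta))^2}{\sigma^2 f_j(\eta)^2}
+ \ln(\sigma^2 f_j(\eta)^2)\right] + \eta'\Omega^{-1}\eta + \ln|2\pi\Omega|$$

is minimized over $\eta$ (the *inner* problem), and the subject's
contribution to the objective function value is the Laplace approximation
$g_i(\hat\eta) + n_i\ln 2\pi - 2\ln 2\pi + \ln\det(H_i/2)$ with $H_i$ the
Hessian of $g_i$ at the mode. Evaluating the residual variance at the
conditional prediction $f(\eta)$ is the "with interaction" feature. The
Laplace form was chosen over the exact FOCE linearization for
implementation clarity: both approximate the same marginal likelihood, and
the Laplace version needs no model-linearization bookkeeping.

Numerical design of the inner problem (2-dimensional, solved for all
subjects simultaneously):

* damped Newton on a 9-point finite-difference stencil (step $10^{-4}$),
  all subjects and all stencil points evaluated in one vectorized pass;
* per-subject backtracking line search, steps capped so a single
  iteration never moves $\eta$ by more than 2, and $|\eta| \le 10$
  overall (an $e^{10}$-fold deviation from typical is already
  unphysiological — the cap only prevents floating-point overflow in
  pathological outer-parameter regions);
* the iteration stops on a gradient tolerance or as soon as no subject
  can improve, whichever comes first; a fully rejected step leaves the
  Laplace term's error far below the objective's numerical precision;
* predictions use `expm1` for the infusion terms (the naive
  $1 - e^{-ku}$ cancels catastrophically for small $ku$), and deep
  underflow of a prediction is floored at $10^{-12}$ mg/L rather than
  rejected, so the likelihood stays finite and steeply repels the
  optimizer from such regions instead of presenting a cliff.

The outer problem runs `nlminb` over
$(\log\theta_1, \theta_3, \theta_4, \log\theta_2, \theta_5, \theta_6,
\log\omega^2_{CL}, \log\omega^2_V, \log\sigma^2)$ — positivity by
log-transform, exponents unconstrained in $[-5, 5]$ — with per-subject
modes warm-started between evaluations. Standard errors come from a
central-difference Hessian of the objective at the optimum with steps of
~0.5% of each parameter (well above the inner-optimization noise floor;
second differences are stable for steps between roughly 0.003 and 0.03),
mapped back to the natural scale by the delta method;
RSE% = 100·SE/estimate. Shrinkages are
$100(1 - SD(\hat\eta)/\sqrt{\omega^2})$ per effect and
$100(1 - SD(\text{IWRES}))$ for the residual.

`nlminb` sometimes reports "false convergence" at a point that is, for
this finite-difference objective, an optimum to within numerical
precision; a fit is therefore classified as converged when the objective
is finite, improved from its starting value, and the optimizer stopped
with any of its convergence messages. Non-converged bootstrap replicates
are dropped and counted (`n_failed`), and the stepwise thresholds
(forward 3.84, backward 6.63 — the $\chi^2_1$ cutoffs at p < 0.05 and
p < 0.01) are configuration fields, since the original analysis does not
record its values.

### Identifiability under the trough/peak design

Two samples per subject support the clearance side of the model well but
leave little per-subject volume information: $\hat\eta_V$ shrinkage near
100% and a boundary-drifting $\hat\omega^2_V$ are *expected* under this
design, and age and weight are so collinear across a pediatric cohort
that the three V-side fixed effects sit on a flat ridge. The package's
recovery tests therefore put tolerances on the CL-side parameters and
$\omega^2_{CL}$, and treat the V-side as ridge-constrained.

### Properties of the conditional objective worth knowing

Two consequences of the interaction term $\ln(\sigma^2 f(\eta)^2)$ that
users of MAP estimates should be aware of (both are exercised in the test
suite):

* with observations lying exactly on the population prediction, the
  conditional mode is *not* exactly zero — the $\ln f^2$ term shifts it
  by $O(\sigma^2)$ (about 0.05 at $\sigma^2 = 0.0749$), vanishing as
  $\sigma^2 \to 0$;
* as $\sigma^2$ grows the mode is pulled away from the data-reproducing
  $\eta$, but its limit is the minimizer of
  $2\sum_j \ln f_j + \eta'\Omega^{-1}\eta$, not the prior mode, so naive
  "shrinkage to zero" statements only hold over moderate noise levels.

## Diagnostics

`cwres()` computes conditional weighted residuals by the standard FOCE
linearization about $\hat\eta$:
$Cov_i = G_i \Omega G_i' + \mathrm{diag}(\sigma^2\hat f_i^2)$ and
$CWRES_i = Cov_i^{-1/2}(y_i - \hat f_i + G_i\hat\eta_i)$, alongside PRED
($f$ at $\eta=0$) and IPRED ($f$ at $\hat\eta$). Under the true model
these behave like standard-normal draws; $|CWRES| = 4$ is the
conventional outlier reference.

`vpc()` simulates replicate datasets under the design of the observed one
and compares binned observed 2.5/50/97.5 percentiles with their
simulation 95% bands. Bins are quantile-based on time since first dose
with a minimum of five observations per bin (small bins merge leftward
with a warning). Note that the band of a percentile converges to a
*fixed-width* interval as the number of replicates grows — it reflects
the sampling variability of that percentile under the model, not Monte
Carlo error — so more replicates stabilize the band rather than shrink
it. `prediction_errors()` (MPE%, MAPE%, RMSE) supports external-validation
style holdout checks; with the study's own holdout cohort unavailable,
the tests validate the machinery on synthetic holdouts.

## PTA simulation and dose recommendation

`simulate_pta()` samples one virtual cohort and one vector of
$\eta_{CL}$ draws per age band (n = 1000 per cell by default; the
original table's varying decimal granularity suggests differing,
unrecorded sizes, and a fixed n is reproducible), then reuses them across
the whole dose × MIC × target grid. AUC-based attainment depends on the
regimen only through the daily dose — AUC~0–24~ = dose/CL is invariant to
splitting q6h/q8h/q12h — and the common random numbers make the scaling
identity PTA(d, m, T) = PTA(2d, 2m, T) = PTA(d, m/2, 2T) exact, which the
tests exploit. Attainment is rounded to one decimal; the `attained` flag
marks cells strictly above 90%. `recommend_regimen()` returns the lowest
simulated daily dose reaching a threshold (default 90%) per (band, MIC,
target) scenario, with `NA` when none does.

Because the virtual-population construction behind the original PTA table
is unrecorded, exact reproduction of its interior percentages is out of
scope; the test surface is the saturated cells (PTA = 100.0 at low MIC),
the exact invariances, the lognormal closed form for a single fixed
patient, and the qualitative age ordering of recommendations.

## Outcome statistics

`fisher_exact_rxc()` enumerates all r×c tables with the observed margins
and sums the probabilities of those no more probable than the observed
table (the probability-ordering two-sided rule — stated explicitly
because r×c two-sided conventions vary); totals above 200 are refused
rather than approximated. `logistic_wald()` wraps an IRLS logistic fit
with per-term Wald χ² (multi-df for categorical terms, most frequent
level as reference) and reports complete separation as inestimable.
`group_summaries()` reproduces the median (IQR) / n (%) table layout with
IQRs suppressed below n = 5, and `mic_summary()` implements the
cumulative-inhibition MIC50/MIC90 definition on the doubling-dilution
grid.

## Problem sizes used by the test suite

Simulation-based tests are sized to demonstrate the statistical property
with comfortable margins while keeping the suite quick: parameter
recovery uses one 300-subject trough/peak cohort plus eight 100-subject
replicates; the stepwise type-I check runs 25 replicates of 40 subjects;
PTA checks use 300–1000 virtual patients per band (the closed-form
single-patient check uses 10⁵); the VPC and CWRES calibration checks use
100–300 subjects and 150–600 replicates. All seeds are fixed in the
tests.

## Known limitations

* One compartment, linear elimination, diagonal $\Omega$, no
  inter-occasion variability, no time-varying covariates.
* The BLQ likelihood handling is exclusion or LOQ/2 imputation, not a
  censored-likelihood (M3) treatment; heavy censoring will bias fits.
* The bedside-Schwartz/Cockcroft–Gault covariate bridge is a pragmatic
  renal-function proxy; in neonates the Schwartz estimate is known to be
  rough.
* Fisher enumeration is exponential in table size; beyond the bound a
  Monte Carlo test (not provided) is the right tool.
* PTA optimizes efficacy attainment only; trough-based safety ceilings
  and nephrotoxicity constraints are outside the package's scope.
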