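# vancoped

Population pharmacokinetics (PK) and dose optimization of vancomycin in
pediatric patients with Gram-positive bacterial infections.

Vancomycin is cleared renally, has high inter-individual variability, and is
dosed against the efficacy index AUC~0–24~/MIC (daily area under the
concentration–time curve over the minimum inhibitory concentration of the
pathogen). In neonates, infants and children the clearance and volume of
distribution change steeply with renal maturation and body size, so adult
regimens cannot simply be scaled down. `vancoped` implements the complete
modelling chain used to address this with sparse routine therapeutic drug
monitoring (TDM) data — typically one trough and one peak sample around the
fifth dose:

1. **Model core** — a one-compartment intermittent-infusion model with the
   unified covariate submodel

   ```
   CL (L/h) = θ1 · (CLCr / 90.28)^θ3 · (WT / 58.25)^θ4 · exp(η_CL)
   V  (L)   = θ2 · (AGE / 55)^θ5 · (WT / 58.25)^θ6 · exp(η_V)
   ```

   with defaults θ1 = 3.83, θ2 = 44.7, θ3 = 0.516, θ4 = 0.646, θ5 = 0.33,
   θ6 = 0.349, inter-individual variances ω²_CL = 0.204, ω²_V = 0.0427 and
   proportional residual variance σ² = 0.0749. Closed forms give the full
   concentration–time profile, steady-state peak/trough, and
   AUC~0–24~ = daily dose / CL.
2. **Nonlinear mixed-effects estimation** — a Laplacian first-order
   conditional (FOCE-type) objective with interaction, stepwise covariate
   selection (forward ΔOFV > 3.84, backward ΔOFV > 6.63), asymptotic
   standard errors, shrinkage, and a nonparametric subject-resampling
   bootstrap.
3. **MAP ("Bayesian feedback") individual estimates** — posterior-mode
   η per subject from sparse TDM, and the individual indices C_min,ss,
   C_max,ss, AUC~0–24~ and AUC~0–24~/MIC.
4. **Monte Carlo PTA** — probability of target attainment over age band ×
   daily dose × MIC × target grids with common random numbers, and
   lowest-attaining-dose regimen recommendation.
5. **Outcome statistics** — logistic regression Wald tests, exact r×c
   contingency-table tests by full enumeration, grouped median/IQR
   summaries, and MIC50/MIC90.
6. **Synthetic cohorts** — a generator for virtual pediatric populations
   (log-uniform ages 6 days–13 years, growth-curve weights and heights,
   age-dependent serum creatinine, bedside-Schwartz creatinine clearance),
   TDM sampling with assay censoring below 3.00 mg/L, and outcome records,
   so that every stage runs and is tested without patient-level data.

## Worked example

Simulate a 108-patient TDM study at 60 mg/kg/day q6h, fit the population
model, derive individual indices, and build a PTA table:

```r
library(vancoped)
p <- population_parameters()            # final-model estimates
cohort <- generate_cohort(cohort_spec(108, "mixed", seed = 1))
ds <- simulate_tdm(cohort, dosing_regimen(daily_dose_per_kg = 60, interval = 6),
                   p, sampling_design(), seed = 2)
fit <- fit_popk(ds, fit_config(init = population_parameters(
  cl_typ = 2, v_typ = 30, clcr_exp = 0.75, wt_exp_cl = 0.75,
  age_exp_v = 0.2, wt_exp_v = 0.5, omega2_cl = 0.1, omega2_v = 0.1,
  sigma2_prop = 0.05)))
fit
#> Population PK fit: 108 subjects, 195 observations (21 BLQ excluded)
#> OFV 1364.682 (initial 1764.443); converged: TRUE
#>     parameter  estimate       se rse_pct     ci_lo     ci_hi estimated
#> 1      cl_typ 2.723e+00 0.584228   21.46  1.577478  3.867654      TRUE
#> 2 cl_CLCR_exp 6.080e-01 0.198946   32.72  0.218096  0.997965      TRUE
#> 3   cl_WT_exp 5.212e-01 0.088860   17.05  0.347038  0.695368      TRUE
#> ...
#> Shrinkage (%): eta_CL 9.1, eta_V 99.1, epsilon 20.8
```

Twenty-one of 216 samples fall below the 3.00 mg/L quantification limit and
are excluded from the likelihood (the default BLQ policy). At this study
size the clearance parameters are recovered with the expected sampling
scatter (the 95% CIs cover the generating values); η_V is heavily shrunk —
a two-sample design carries almost no volume information per subject, which
is exactly the pattern routine trough/peak TDM produces.

```r
idx <- map_indices(ds, p, mic = 1)      # MAP Bayesian individual indices
round(quantile(idx$auc24, c(.25, .5, .75)), 1)
#>   25%   50%   75%
#> 282.5 367.6 520.6

tab <- simulate_pta(pta_grid_spec(n = 1000, seed = 3), p)
subset(recommend_regimen(tab), mic == 1 & target == 200)
#>  age_band mic target recommended_dose pta_at_dose
#>      0-3m   1    200               70        91.7
#>    3m-12y   1    200               60        92.3
#>   12y-17y   1    200               40        96.8
```

The recommendation table reads: to reach AUC~0–24~/MIC ≥ 200 in at least
90% of patients at MIC 1 mg/L, infants under 3 months need ~70 mg/kg/day,
children 3 months–12 years ~60 mg/kg/day, and adolescents attain it already
at 40 mg/kg/day — older pediatric patients reach the same target at lower
weight-normalized doses.

See `vignettes/vancomycin-pediatric-popkpd.Rmd` for the model, estimation
method, generator design and numerical choices in detail.

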