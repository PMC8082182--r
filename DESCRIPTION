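Package: vancoped
Title: Population Pharmacokinetics and Dose Optimization of Vancomycin in
    Pediatric Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (PK) analysis of vancomycin
    therapeutic drug monitoring (TDM) data in pediatric patients. Implements a
    one-compartment intermittent-infusion model with a unified covariate
    submodel (creatinine clearance and body weight on clearance; age and body
    weight on volume), nonlinear mixed-effects estimation by a Laplacian
    first-order conditional (FOCE-type) objective with interaction, stepwise
    covariate selection, nonparametric bootstrap, goodness-of-fit and visual
    predictive check diagnostics, maximum a posteriori (MAP) Bayesian
    estimation of individual PK/PD indices from sparse TDM samples, Monte
    Carlo probability-of-target-attainment (PTA) simulation over AUC/MIC
    targets for dose-regimen selection, and the accompanying clinical and
    microbiological outcome statistics (logistic Wald tests, exact
    contingency-table tests, MIC distribution summaries). A synthetic-data
    module generates virtual pediatric cohorts, TDM observations and outcome
    records with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
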