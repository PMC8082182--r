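#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, inter-individual variability (IIV)
#' variances and residual-error variance of the one-compartment vancomycin
#' population model with covariates on clearance (creatinine clearance, body
#' weight) and volume (age, body weight):
#'
#' \deqn{CL = \theta_1 (CLCr/90.28)^{\theta_3} (WT/58.25)^{\theta_4} e^{\eta_{CL}}}
#' \deqn{V  = \theta_2 (AGE/55)^{\theta_5} (WT/58.25)^{\theta_6} e^{\eta_V}}
#'
#' Defaults are the final-model estimates of the unified adult/pediatric
#' vancomycin model. The \code{omega2_*} values are variances of normally
#' distributed \eqn{\eta} (so the approximate IIV CV is
#' \code{100*sqrt(omega2)} percent); \code{sigma2_prop} is the variance of a
#' proportional residual error, \eqn{y = f (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}.
#'
#' @param cl_typ typical clearance (L/h) at the reference covariates.
#' @param v_typ typical volume of distribution (L) at the reference covariates.
#' @param clcr_exp exponent of creatinine clearance on CL.
#' @param wt_exp_cl exponent of body weight on CL.
#' @param age_exp_v exponent of age on V.
#' @param wt_exp_v exponent of body weight on V.
#' @param clcr_ref reference creatinine clearance (mL/min).
#' @param wt_ref reference body weight (kg).
#' @param age_ref reference age (years).
#' @param omega2_cl IIV variance of \eqn{\eta_{CL}}.
#' @param omega2_v IIV variance of \eqn{\eta_V}.
#' @param sigma2_prop proportional residual-error variance.
#' @return An object of class \code{population_parameters}.
#' @examples
#' p <- population_parameters()
#' p$cl_typ # 3.83 L/h
#' @export
population_parameters <- function(cl_typ = 3.83, v_typ = 44.7,
                                  clcr_exp = 0.516, wt_exp_cl = 0.646,
                                  age_exp_v = 0.33, wt_exp_v = 0.349,
                                  clcr_ref = 90.28, wt_ref = 58.25,
                                  age_ref = 55,
                                  omega2_cl = 0.204, omega2_v = 0.0427,
                                  sigma2_prop = 0.0749) {
  p <- list(cl_typ = cl_typ, v_typ = v_typ,
            clcr_exp = clcr_exp, wt_exp_cl = wt_exp_cl,
            age_exp_v = age_exp_v, wt_exp_v = wt_exp_v,
            clcr_ref = clcr_ref, wt_ref = wt_ref, age_ref = age_ref,
            omega2_cl = omega2_cl, omega2_v = omega2_v,
            sigma2_prop = sigma2_prop)
  for (nm in c("cl_typ", "v_typ", "clcr_ref", "wt_ref", "age_ref")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  }
  for (nm in c("omega2_cl", "omega2_v", "sigma2_prop")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("'", nm, "' must be a non-negative variance", call. = FALSE)
  }
  structure(p, class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Population PK parameters (one-compartment, covariate submodel)\n")
  cat(sprintf("  CL typ %.3g L/h x (CLCr/%.4g)^%.3g x (WT/%.4g)^%.3g\n",
              x$cl_typ, x$clcr_ref, x$clcr_exp, x$wt_ref, x$wt_exp_cl))
  cat(sprintf("  V  typ %.3g L   x (AGE/%.4g)^%.3g x (WT/%.4g)^%.3g\n",
              x$v_typ, x$age_ref, x$age_exp_v, x$wt_ref, x$wt_exp_v))
  cat(sprintf("  omega2_CL %.4g  omega2_V %.4g  sigma2(prop) %.4g\n",
              x$omega2_cl, x$omega2_v, x$sigma2_prop))
  invisible(x)
}

#' Patient covariates
#'
#' Builds a covariate table (one row per patient). Creatinine clearance may
#' be supplied directly in \code{clcr} or derived later with
#' \code{\link{creatinine_clearance}}.
#'
#' @param age age in decimal years (postnatal age for neonates), > 0.
#' @param weight body weight (kg), > 0.
#' @param height height (m); required to derive pediatric creatinine
#'   clearance.
#' @param scr serum creatinine (umol/L), > 0.
#' @param clcr creatinine clearance (mL/min), optional.
#' @param sex \code{"M"} or \code{"F"}; used only by the adult
#'   Cockcroft-Gault branch.
#' @param id subject identifiers; defaults to \code{1:n}.
#' @return A \code{data.frame} of class \code{patient_covariates} with columns
#'   \code{ID, AGE, WT, HT, SCR, CLCR, SEX}.
#' @export
patient_covariates <- function(age, weight, height = NA_real_, scr = NA_real_,
                               clcr = NA_real_, sex = NA_character_,
                               id = NULL) {
  n <- max(length(age), length(weight))
  if (is.null(id)) id <- seq_len(n)
  cov <- data.frame(ID = id, AGE = age, WT = weight, HT = height,
                    SCR = scr, CLCR = clcr, SEX = sex,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(cov$AGE) | cov$AGE < 0))
    stop("covariate 'AGE' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(cov$WT) | cov$WT <= 0))
    stop("covariate 'WT' must be strictly positive", call. = FALSE)
  if (any(!is.na(cov$SCR) & cov$SCR <= 0))
    stop("covariate 'SCR' must be strictly positive", call. = FALSE)
  if (any(!is.na(cov$CLCR) & cov$CLCR <= 0))
    stop("covariate 'CLCR' must be strictly positive", call. = FALSE)
  class(cov) <- c("patient_covariates", "data.frame")
  cov
}

#' Intermittent-infusion dosing regimen
#'
#' @param dose dose per administration (mg). Either \code{dose} or
#'   \code{daily_dose_per_kg} together with \code{weight} must be given.
#' @param interval dosing interval tau (h), typically 6, 8 or 12.
#' @param infusion_duration infusion duration (h); default 1 h.
#' @param n_doses number of administered doses (dose events), default 5 (the
#'   trough/peak TDM design samples around the fifth dose).
#' @param daily_dose_per_kg daily dose (mg/kg/day), used with \code{weight}.
#' @param weight body weight (kg), used with \code{daily_dose_per_kg}.
#' @return An object of class \code{dosing_regimen} with fields \code{dose},
#'   \code{interval}, \code{infusion_duration}, \code{n_doses},
#'   \code{daily_dose} (mg/day) and, when available, \code{daily_dose_per_kg}.
#' @export
dosing_regimen <- function(dose = NULL, interval = 6, infusion_duration = 1,
                           n_doses = 5, daily_dose_per_kg = NULL,
                           weight = NULL) {
  if (is.null(dose)) {
    if (is.null(daily_dose_per_kg))
      stop("supply either 'dose' or 'daily_dose_per_kg'", call. = FALSE)
    # without a weight the regimen stays on the mg/kg scale; per-subject
    # doses are resolved where the weight is known (e.g. simulate_tdm)
    dose <- if (is.null(weight)) NA_real_ else
      daily_dose_per_kg * weight / (24 / interval)
  }
  if (any(!is.na(dose) & dose <= 0))
    stop("'dose' must be positive", call. = FALSE)
  if (infusion_duration <= 0 || infusion_duration >= interval)
    stop("'infusion_duration' must satisfy 0 < duration < interval",
         call. = FALSE)
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses,
                 daily_dose = dose * 24 / interval,
                 daily_dose_per_kg = daily_dose_per_kg),
            class = "dosing_regimen")
}
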