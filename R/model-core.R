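#' Individual clearance from the covariate model
#'
#' Evaluates
#' \eqn{CL = \theta_1 (CLCr/CLCr_{ref})^{\theta_3} (WT/WT_{ref})^{\theta_4} e^{\eta_{CL}}}.
#' At the reference covariates (CLCr 90.28 mL/min, WT 58.25 kg) and
#' \eqn{\eta = 0} this returns the typical value \code{p$cl_typ}.
#'
#' @param cov a \code{\link{patient_covariates}} table (or any data.frame
#'   with columns \code{CLCR} and \code{WT}); vectorized over rows.
#' @param eta_cl random effect(s) on CL (dimensionless), recycled.
#' @param p \code{\link{population_parameters}}.
#' @return Clearance in L/h, one value per row of \code{cov}.
#' @export
clearance <- function(cov, eta_cl = 0, p = population_parameters()) {
  clcr <- cov$CLCR
  wt <- cov$WT
  if (is.null(clcr) || any(is.na(clcr)))
    stop("covariate 'CLCR' is missing; derive it with creatinine_clearance()",
         call. = FALSE)
  if (any(clcr <= 0)) stop("covariate 'CLCR' must be positive", call. = FALSE)
  if (is.null(wt) || any(is.na(wt) | wt <= 0))
    stop("covariate 'WT' must be present and positive", call. = FALSE)
  p$cl_typ * (clcr / p$clcr_ref)^p$clcr_exp * (wt / p$wt_ref)^p$wt_exp_cl *
    exp(eta_cl)
}

#' Individual volume of distribution from the covariate model
#'
#' Evaluates
#' \eqn{V = \theta_2 (AGE/AGE_{ref})^{\theta_5} (WT/WT_{ref})^{\theta_6} e^{\eta_V}}.
#' Age must be strictly positive (postnatal age in decimal years for
#' neonates): age zero would collapse the power term.
#'
#' @inheritParams clearance
#' @param eta_v random effect(s) on V (dimensionless), recycled.
#' @return Volume in L, one value per row of \code{cov}.
#' @export
volume <- function(cov, eta_v = 0, p = population_parameters()) {
  age <- cov$AGE
  wt <- cov$WT
  if (is.null(age) || any(is.na(age) | age <= 0))
    stop("covariate 'AGE' must be present and strictly positive (postnatal age in years)",
         call. = FALSE)
  if (is.null(wt) || any(is.na(wt) | wt <= 0))
    stop("covariate 'WT' must be present and positive", call. = FALSE)
  p$v_typ * (age / p$age_ref)^p$age_exp_v * (wt / p$wt_ref)^p$wt_exp_v *
    exp(eta_v)
}

#' Estimate creatinine clearance
#'
#' Fills the \code{CLCR} covariate. Rows with a supplied \code{CLCR} are
#' passed through unchanged. For subjects aged 18 or older, the
#' Cockcroft-Gault equation is used (serum creatinine converted from umol/L
#' to mg/dL by 1/88.42; female values scaled by 0.85). For pediatric
#' subjects, the bedside Schwartz estimate
#' \eqn{0.413 \times height_{cm} / SCr_{mg/dL}} is used. By default the
#' Schwartz value (which is on the mL/min/1.73 m\eqn{^2} scale) is used
#' directly as the \code{CLCR} covariate; \code{scale = "absolute"} instead
#' converts it to absolute mL/min by the Mosteller body-surface-area ratio
#' BSA/1.73.
#'
#' @param cov a \code{\link{patient_covariates}} table.
#' @param scale pediatric scale: \code{"normalized"} (default, bedside
#'   Schwartz used as-is) or \code{"absolute"} (scaled by BSA/1.73).
#' @return Numeric vector of creatinine clearance values (mL/min), one per
#'   row.
#' @export
creatinine_clearance <- function(cov, scale = c("normalized", "absolute")) {
  scale <- match.arg(scale)
  out <- cov$CLCR
  if (is.null(out)) out <- rep(NA_real_, nrow(cov))
  todo <- is.na(out)
  if (!any(todo)) return(out)
  if (any(is.na(cov$SCR[todo]) | cov$SCR[todo] <= 0))
    stop("covariate 'SCR' must be positive to derive creatinine clearance",
         call. = FALSE)
  scr_mgdl <- cov$SCR / 88.42
  adult <- todo & cov$AGE >= 18
  if (any(adult)) {
    if (any(is.na(cov$SEX[adult])))
      stop("covariate 'SEX' required for adult Cockcroft-Gault", call. = FALSE)
    cg <- (140 - cov$AGE) * cov$WT / (72 * scr_mgdl)
    cg <- cg * ifelse(cov$SEX == "F", 0.85, 1)
    out[adult] <- cg[adult]
  }
  ped <- todo & cov$AGE < 18
  if (any(ped)) {
    if (any(is.na(cov$HT[ped]) | cov$HT[ped] <= 0))
      stop("covariate 'HT' (height, m) required for pediatric Schwartz estimate",
           call. = FALSE)
    egfr <- 0.413 * (cov$HT * 100) / scr_mgdl
    if (scale == "absolute") {
      bsa <- sqrt(cov$HT * 100 * cov$WT / 3600) # Mosteller
      egfr <- egfr * bsa / 1.73
    }
    out[ped] <- egfr[ped]
  }
  out
}

# Piecewise closed form for a single zero-order infusion started at time 0:
# during infusion C = (R0/CL)(1 - exp(-k t)); after it the end-of-infusion
# concentration decays mono-exponentially.
infusion_conc <- function(dt, rate, dur, cl, k) {
  up <- pmin(dt, dur)
  out <- (rate / cl) * (-expm1(-k * pmax(up, 0))) * exp(-k * pmax(dt - dur, 0))
  out[dt <= 0] <- 0
  out
}

#' Concentration-time profile under repeated intermittent infusion
#'
#' Closed-form one-compartment superposition of the infusion segments of a
#' \code{\link{dosing_regimen}} (doses at \code{0, tau, 2*tau, ...}), with
#' elimination rate \eqn{k = CL/V}. Continuous and non-negative in \code{t};
#' zero before the first dose.
#'
#' @param cl clearance (L/h), scalar.
#' @param v volume (L), scalar.
#' @param regimen a \code{\link{dosing_regimen}}; \code{regimen$n_doses}
#'   doses are administered.
#' @param t time(s) in h since the start of the first infusion; vectorized.
#' @return Concentration(s) in mg/L.
#' @export
concentration_at_time <- function(cl, v, regimen, t) {
  stopifnot(cl > 0, v > 0)
  k <- cl / v
  rate <- regimen$dose / regimen$infusion_duration
  dose_times <- (seq_len(regimen$n_doses) - 1) * regimen$interval
  out <- numeric(length(t))
  for (t0 in dose_times) {
    out <- out + infusion_conc(t - t0, rate, regimen$infusion_duration, cl, k)
  }
  out
}

#' Steady-state peak and trough concentrations
#'
#' Closed forms for repeated intermittent infusion at steady state: the peak
#' (end of infusion) is
#' \eqn{C_{max,ss} = (R_0/CL)(1-e^{-k T_{inf}})/(1-e^{-k\tau})} and the trough
#' \eqn{C_{min,ss} = C_{max,ss} e^{-k(\tau - T_{inf})}}.
#'
#' @inheritParams concentration_at_time
#' @return A list with components \code{cmax_ss} and \code{cmin_ss} (mg/L);
#'   vectorized over \code{cl}, \code{v}.
#' @export
steady_state_indices <- function(cl, v, regimen) {
  stopifnot(all(cl > 0), all(v > 0))
  k <- cl / v
  tau <- regimen$interval
  tinf <- regimen$infusion_duration
  rate <- regimen$dose / tinf
  cmax <- (rate / cl) * (-expm1(-k * tinf)) / (-expm1(-k * tau))
  cmin <- cmax * exp(-k * (tau - tinf))
  list(cmax_ss = cmax, cmin_ss = cmin)
}

#' Steady-state daily area under the curve
#'
#' For linear PK at steady state the 24-h AUC equals daily dose / clearance.
#'
#' @param daily_dose total daily dose (mg/day).
#' @param cl clearance (L/h).
#' @return AUC over 24 h (mg*h/L).
#' @export
auc24_ss <- function(daily_dose, cl) {
  if (any(cl <= 0)) stop("'cl' must be positive", call. = FALSE)
  daily_dose / cl
}
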