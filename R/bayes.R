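#' MAP ("Bayesian feedback") estimate of individual random effects
#'
#' Minimizes \code{\link{subject_conditional_objective}} over
#' \eqn{\eta = (\eta_{CL}, \eta_V)} with the population parameters held
#' fixed. With no usable observations the prior mode \eqn{\eta = (0, 0)} is
#' returned. BLQ observations are excluded by default, consistent with the
#' fitting policy.
#'
#' @param records a single subject's rows of a \code{\link{tdm_dataset}}.
#' @param p \code{\link{population_parameters}}.
#' @param include_blq include BLQ rows (LLOQ/2) in the objective?
#' @return A list of class \code{map_estimate}: \code{eta_cl}, \code{eta_v},
#'   \code{objective}, \code{hessian} (2x2 posterior curvature),
#'   \code{n_obs}, \code{n_blq_excluded}, \code{convergence}.
#' @export
map_eta <- function(records, p = population_parameters(),
                    include_blq = FALSE) {
  prep <- prepare_nlme(tdm_dataset(as.data.frame(records)),
                       include_blq = include_blq)
  if (prep$n_obs == 0) {
    return(structure(list(eta_cl = 0, eta_v = 0, objective = NA_real_,
                          hessian = diag(2 / c(p$omega2_cl, p$omega2_v)),
                          n_obs = 0L, n_blq_excluded = prep$n_blq_excluded,
                          convergence = TRUE),
                     class = "map_estimate"))
  }
  cov <- prep$cov
  base_lcl <- log(clearance(cov, 0, p))
  base_lv <- log(volume(cov, 0, p))
  gfun <- function(eta) g_all(prep, base_lcl, base_lv,
                              c(p$omega2_cl, p$omega2_v), p$sigma2_prop, eta)
  sol <- inner_newton(gfun, matrix(0, 1, 2), max_iter = 100L, tol = 1e-9)
  H <- matrix(c(sol$gxx, sol$gxy, sol$gxy, sol$gyy), 2, 2) / 2
  conv <- is.finite(sol$grad_max) && sol$grad_max < 1e-4
  if (!conv)
    warning("MAP optimization did not reach the gradient tolerance ",
            "(last |grad| = ", format(sol$grad_max), ")", call. = FALSE)
  structure(list(eta_cl = sol$eta[1, 1], eta_v = sol$eta[1, 2],
                 objective = sol$g[1], hessian = H, n_obs = prep$n_obs,
                 n_blq_excluded = prep$n_blq_excluded, convergence = conv),
            class = "map_estimate")
}

#' Individual steady-state PK/PD indices
#'
#' Derives the individual clearance and volume from the covariate model
#' with the subject's \eqn{\eta}, then the steady-state peak and trough
#' under the regimen, the 24-h AUC (daily dose / CL) and AUC/MIC.
#'
#' @param cov single-row \code{\link{patient_covariates}}.
#' @param eta numeric length-2 \code{c(eta_cl, eta_v)} or a
#'   \code{map_estimate}.
#' @param p \code{\link{population_parameters}}.
#' @param regimen a \code{\link{dosing_regimen}}.
#' @param mic minimum inhibitory concentration (mg/L), > 0; default 1 (the
#'   cohort MIC50).
#' @return A list of class \code{derived_indices}: \code{cl_i}, \code{v_i},
#'   \code{cmin_ss}, \code{cmax_ss}, \code{auc24}, \code{auc24_over_mic},
#'   \code{mic}.
#' @export
derive_indices <- function(cov, eta, p, regimen, mic = 1) {
  if (inherits(eta, "map_estimate")) eta <- c(eta$eta_cl, eta$eta_v)
  if (mic <= 0) stop("'mic' must be positive", call. = FALSE)
  cl_i <- clearance(cov, eta[1], p)
  v_i <- volume(cov, eta[2], p)
  ss <- steady_state_indices(cl_i, v_i, regimen)
  auc <- auc24_ss(regimen$daily_dose, cl_i)
  structure(list(cl_i = cl_i, v_i = v_i, cmin_ss = ss$cmin_ss,
                 cmax_ss = ss$cmax_ss, auc24 = auc,
                 auc24_over_mic = auc / mic, mic = mic),
            class = "derived_indices")
}

# Reconstruct a per-subject maintenance regimen from the dosing history:
# interval = median gap between doses, amount = last dose.
infer_regimen <- function(records, infusion_duration = NULL) {
  doses <- records[records$EVID == 1, , drop = FALSE]
  if (nrow(doses) == 0) stop("subject has no dose records", call. = FALSE)
  doses <- doses[order(doses$TIME), , drop = FALSE]
  interval <- if (nrow(doses) > 1)
    stats::median(diff(doses$TIME)) else 6
  amt <- doses$AMT[nrow(doses)]
  dur <- if (!is.null(infusion_duration)) infusion_duration else
    amt / doses$RATE[nrow(doses)]
  dosing_regimen(dose = amt, interval = interval, infusion_duration = dur,
                 n_doses = nrow(doses))
}

#' Per-subject MAP PK/PD index table
#'
#' Runs \code{\link{map_eta}} and \code{\link{derive_indices}} for every
#' subject of a TDM dataset. The maintenance regimen is reconstructed from
#' each subject's dosing history; the MIC comes from \code{mic} (a single
#' value, a named vector by subject ID, or a column name in \code{ds}).
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param p \code{\link{population_parameters}}.
#' @param mic MIC source; default 1 mg/L.
#' @param include_blq include BLQ rows in the MAP objectives?
#' @return A data.frame with one row per subject: ID, eta pair, individual
#'   CL/V, steady-state trough/peak, AUC24 and AUC24/MIC.
#' @export
map_indices <- function(ds, p = population_parameters(), mic = 1,
                        include_blq = FALSE) {
  ids <- unique(ds$ID)
  mic_of <- function(id, sub) {
    if (is.character(mic) && length(mic) == 1 && mic %in% names(ds))
      return(sub[[mic]][1])
    if (!is.null(names(mic))) return(unname(mic[as.character(id)]))
    mic
  }
  rows <- lapply(ids, function(id) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    m <- map_eta(sub, p, include_blq = include_blq)
    reg <- infer_regimen(sub)
    cov <- tdm_covariates(tdm_dataset(as.data.frame(sub)))
    di <- derive_indices(cov, m, p, reg, mic = mic_of(id, sub))
    data.frame(ID = id, eta_cl = m$eta_cl, eta_v = m$eta_v, n_obs = m$n_obs,
               n_blq_excluded = m$n_blq_excluded, cl_i = di$cl_i,
               v_i = di$v_i, cmin_ss = di$cmin_ss, cmax_ss = di$cmax_ss,
               auc24 = di$auc24, mic = di$mic,
               auc24_over_mic = di$auc24_over_mic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
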