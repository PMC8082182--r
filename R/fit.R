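#' Conditional (subject-level) objective
#'
#' The -2 log of the product of the proportional-error likelihood and the
#' random-effect prior for one subject:
#' \deqn{\sum_j \left[ \frac{(y_j - f_j)^2}{\sigma^2 f_j^2} +
#'   \ln(\sigma^2 f_j^2) \right] + \eta' \Omega^{-1} \eta + \ln|2\pi\Omega|}
#' with \eqn{f_j} the model prediction at the subject's dosing history and
#' \eqn{\eta = (\eta_{CL}, \eta_V)}. This is the inner objective of the
#' FOCE-type estimation and the MAP ("Bayesian feedback") objective.
#'
#' @param records the subject's rows of a \code{\link{tdm_dataset}} (doses
#'   and observations, single subject).
#' @param p \code{\link{population_parameters}}.
#' @param eta numeric length-2, \code{c(eta_cl, eta_v)}.
#' @param include_blq include BLQ rows (imputed at LLOQ/2)? Default exclude.
#' @return The scalar objective value.
#' @export
subject_conditional_objective <- function(records, p, eta,
                                          include_blq = FALSE) {
  if (length(unique(records$ID)) != 1)
    stop("'records' must belong to a single subject", call. = FALSE)
  prep <- prepare_nlme(tdm_dataset(as.data.frame(records)),
                       include_blq = include_blq)
  if (prep$n_obs < 1)
    stop("subject has no usable (non-BLQ) observations", call. = FALSE)
  cov <- prep$cov
  base_lcl <- log(clearance(cov, 0, p))
  base_lv <- log(volume(cov, 0, p))
  g_all(prep, base_lcl, base_lv, c(p$omega2_cl, p$omega2_v), p$sigma2_prop,
        matrix(eta, 1, 2))
}

#' FOCE-type marginal objective function value
#'
#' Sum over subjects of the Laplace-approximated marginal -2 log-likelihood
#' with interaction, evaluated at the inner-optimized random-effect modes.
#' Deterministic given the data and parameters.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param p \code{\link{population_parameters}}.
#' @param struct a \code{\link{pk_structure}} (defaults to the final
#'   covariate model).
#' @param include_blq include BLQ rows (LLOQ/2) in the likelihood?
#' @return The objective function value (OFV); the per-subject modes are
#'   attached as \code{attr(, "eta")}.
#' @export
foce_objective <- function(ds, p, struct = pk_structure(),
                           include_blq = FALSE) {
  prep <- prepare_nlme(ds, struct, include_blq = include_blq)
  oo <- make_outer_objective(prep, struct)
  val <- oo$objective(pack_params(p, struct))
  if (val >= 1e10)
    stop("inner optimization failed for at least one subject", call. = FALSE)
  attr(val, "eta") <- oo$env$eta
  val
}

#' Fitting configuration
#'
#' @param init initial \code{\link{population_parameters}}.
#' @param model a \code{\link{pk_structure}} describing the covariate model.
#' @param estimate character vector of packed parameter names to estimate
#'   (see \code{\link{pk_structure}}; names follow
#'   \code{log_cl_typ, cl_<COV>_exp, log_v_typ, v_<COV>_exp, log_omega2_cl,
#'   log_omega2_v, log_sigma2}); \code{NULL} estimates everything.
#' @param max_iter maximum outer iterations.
#' @param rel_tol outer relative convergence tolerance.
#' @param inner_tol inner (eta) gradient tolerance.
#' @param include_blq include BLQ rows (LLOQ/2) in the likelihood?
#' @param compute_se compute asymptotic standard errors from the numerical
#'   Hessian (adds a modest cost)?
#' @param forward_dofv,backward_dofv OFV-drop thresholds for stepwise
#'   covariate inclusion (default 3.84, p < 0.05 at 1 df) and retention
#'   (default 6.63, p < 0.01).
#' @return A list of class \code{fit_config}.
#' @export
fit_config <- function(init = population_parameters(),
                       model = pk_structure(), estimate = NULL,
                       max_iter = 200L, rel_tol = 1e-7, inner_tol = 1e-7,
                       include_blq = FALSE, compute_se = TRUE,
                       forward_dofv = 3.84, backward_dofv = 6.63) {
  stopifnot(rel_tol > 0, inner_tol > 0, max_iter >= 1)
  structure(list(init = init, model = model, estimate = estimate,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 inner_tol = inner_tol, include_blq = include_blq,
                 compute_se = compute_se, forward_dofv = forward_dofv,
                 backward_dofv = backward_dofv),
            class = "fit_config")
}

#' Fit the population PK model
#'
#' Minimizes the FOCE-type (Laplacian, with interaction) objective over the
#' fixed effects and variance components. Positivity of typical values and
#' variances is enforced by log-transformation; covariate exponents are
#' unconstrained. Standard errors come from the numerical Hessian of the
#' objective; shrinkages are \eqn{100 (1 - SD(\hat\eta)/\sqrt{\omega^2})}
#' for each random effect and \eqn{100 (1 - SD(IWRES))} for the residual.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param cfg a \code{\link{fit_config}}.
#' @return An object of class \code{popk_fit}: a list with elements
#'   \code{estimates} (named natural-scale vector), \code{params}
#'   (\code{\link{population_parameters}} when the structure is the
#'   canonical final model), \code{table} (estimate/SE/RSE\%/95\% CI),
#'   \code{ofv}, \code{eta} (per-subject modes), \code{shrinkage},
#'   \code{convergence}, \code{n_subjects}, \code{n_obs}.
#' @export
fit_popk <- function(ds, cfg = fit_config()) {
  struct <- cfg$model
  prep <- prepare_nlme(ds, struct, include_blq = cfg$include_blq)
  if (prep$n_subj < 20)
    warning("fewer than 20 subjects; population estimates may be unstable",
            call. = FALSE)
  start_full <- pack_params(cfg$init, struct)
  nm <- names(start_full)
  est_mask <- if (is.null(cfg$estimate)) rep(TRUE, length(nm)) else {
    unknown <- setdiff(cfg$estimate, nm)
    if (length(unknown))
      stop("unknown parameter(s) in 'estimate': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    nm %in% cfg$estimate
  }
  oo <- make_outer_objective(prep, struct, inner_tol = cfg$inner_tol)
  full <- start_full
  obj_est <- function(pe) {
    full[est_mask] <- pe
    oo$objective(full)
  }
  is_log <- grepl("^log_", nm)
  lower <- ifelse(is_log, -15, -5)[est_mask]
  upper <- ifelse(is_log, 15, 5)[est_mask]
  ofv0 <- obj_est(start_full[est_mask])
  opt <- stats::nlminb(start_full[est_mask], obj_est,
                       lower = lower, upper = upper,
                       control = list(iter.max = cfg$max_iter,
                                      eval.max = 10 * cfg$max_iter,
                                      rel.tol = cfg$rel_tol))
  full[est_mask] <- opt$par
  # nlminb's "false/singular convergence" codes near an optimum are benign
  # for this finite-difference objective; require only a finite improved
  # objective plus either a clean code or one of those stopping messages
  converged <- is.finite(opt$objective) && opt$objective < 1e9 &&
    opt$objective <= ofv0 + 1e-6 &&
    (opt$convergence == 0 ||
       grepl("convergence", opt$message, ignore.case = TRUE))
  if (!converged)
    warning("optimizer did not converge (code ", opt$convergence, "): ",
            opt$message, call. = FALSE)

  # final inner pass at the optimum
  ofv <- oo$objective(full)
  eta_hat <- oo$env$eta
  th <- unpack_params(full, struct)

  natural <- c(th$cl_typ, th$cl_exp, th$v_typ, th$v_exp, th$omega2, th$sigma2)
  names(natural) <- sub("^log_", "", nm)

  se_nat <- rep(NA_real_, length(nm))
  if (cfg$compute_se) {
    H <- tryCatch(num_hessian(obj_est, full[est_mask]),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv) && all(is.finite(diag(cv))) && all(diag(cv) > 0)) {
        se_t <- sqrt(diag(cv))
        # delta method back to natural scale for log-parameters
        scale <- ifelse(is_log[est_mask], exp(full[est_mask]), 1)
        se_nat[est_mask] <- se_t * scale
      }
    }
  }
  tab <- data.frame(
    parameter = names(natural), estimate = unname(natural),
    se = se_nat, rse_pct = 100 * se_nat / abs(natural),
    ci_lo = natural - 1.96 * se_nat, ci_hi = natural + 1.96 * se_nat,
    estimated = est_mask, row.names = NULL)

  shr <- c(eta_cl = NA_real_, eta_v = NA_real_, epsilon = NA_real_)
  if (prep$n_subj >= 2) {
    shr["eta_cl"] <- 100 * (1 - stats::sd(eta_hat[, 1]) / sqrt(th$omega2[1]))
    shr["eta_v"] <- 100 * (1 - stats::sd(eta_hat[, 2]) / sqrt(th$omega2[2]))
    base_lcl <- log(th$cl_typ) + as.numeric(prep$Xcl %*% th$cl_exp)
    base_lv <- log(th$v_typ) + as.numeric(prep$Xv %*% th$v_exp)
    f_ind <- predict_conc(prep, base_lcl + eta_hat[, 1],
                          base_lv + eta_hat[, 2])
    iwres <- (prep$obs_y - f_ind) / (sqrt(th$sigma2) * f_ind)
    shr["epsilon"] <- 100 * (1 - stats::sd(iwres))
  }

  params <- if (is_canonical_structure(struct))
    population_parameters(cl_typ = th$cl_typ, v_typ = th$v_typ,
                          clcr_exp = th$cl_exp[["CLCR"]],
                          wt_exp_cl = th$cl_exp[["WT"]],
                          age_exp_v = th$v_exp[["AGE"]],
                          wt_exp_v = th$v_exp[["WT"]],
                          clcr_ref = attr(prep$Xcl, "refs")[["CLCR"]],
                          wt_ref = attr(prep$Xcl, "refs")[["WT"]],
                          age_ref = attr(prep$Xv, "refs")[["AGE"]],
                          omega2_cl = th$omega2[1], omega2_v = th$omega2[2],
                          sigma2_prop = th$sigma2)
  else NULL

  structure(list(estimates = natural, params = params, table = tab,
                 ofv = as.numeric(ofv), ofv_initial = as.numeric(ofv0),
                 eta = eta_hat, ids = prep$ids, shrinkage = shr,
                 convergence = converged, opt = opt, model = struct,
                 cfg = cfg, n_subjects = prep$n_subj, n_obs = prep$n_obs,
                 n_blq_excluded = prep$n_blq_excluded),
            class = "popk_fit")
}

#' @export
print.popk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations (%d BLQ excluded)\n",
              x$n_subjects, x$n_obs, x$n_blq_excluded))
  cat(sprintf("OFV %.3f (initial %.3f); converged: %s\n",
              x$ofv, x$ofv_initial, x$convergence))
  print(x$table, digits = 4)
  cat(sprintf("Shrinkage (%%): eta_CL %.1f, eta_V %.1f, epsilon %.1f\n",
              x$shrinkage["eta_cl"], x$shrinkage["eta_v"],
              x$shrinkage["epsilon"]))
  invisible(x)
}

#' Stepwise covariate selection
#'
#' Forward selection adds, one at a time, the candidate covariate (as a
#' power law normalized at the sample median) whose inclusion drops the OFV
#' the most, provided the drop exceeds \code{cfg$forward_dofv} (default
#' 3.84, chi-squared p < 0.05 at 1 df). Backward elimination then removes
#' forward-selected covariates whose removal increases the OFV by less than
#' \code{cfg$backward_dofv} (default 6.63, p < 0.01). Ties break
#' deterministically by candidate order.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param candidates data.frame with columns \code{param} (\code{"cl"} or
#'   \code{"v"}) and \code{covariate} (a dataset column name).
#' @param cfg a \code{\link{fit_config}}; its \code{model} is the base
#'   structure (default base: no covariates).
#' @return A list of class \code{stepwise_result}: \code{structure} (the
#'   selected \code{\link{pk_structure}}), \code{fit} (final
#'   \code{popk_fit}), \code{trace} (data.frame of tested steps).
#' @export
stepwise_covariates <- function(ds, candidates,
                                cfg = fit_config(model = pk_structure(
                                  cl_cov = c(), v_cov = c()))) {
  struct <- cfg$model
  cand <- candidates
  if (nrow(cand)) {
    covs <- ds[!duplicated(ds$ID), , drop = FALSE]
    lc <- lapply(unique(cand$covariate), function(nm) log(covs[[nm]]))
    if (length(lc) > 1) {
      cc <- stats::cor(do.call(cbind, lc))
      if (any(abs(cc[upper.tri(cc)]) > 0.99))
        warning("nearly collinear candidate covariates; selection order ",
                "breaks ties deterministically", call. = FALSE)
    }
  }
  refit <- function(st) {
    c2 <- cfg
    c2$model <- st
    c2$compute_se <- FALSE
    fit_popk(ds, c2)
  }
  add_cov <- function(st, param, covariate) {
    if (param == "cl") st$cl_cov <- c(st$cl_cov, stats::setNames(NA_real_, covariate))
    else st$v_cov <- c(st$v_cov, stats::setNames(NA_real_, covariate))
    st
  }
  drop_cov <- function(st, param, covariate) {
    if (param == "cl") st$cl_cov <- st$cl_cov[names(st$cl_cov) != covariate]
    else st$v_cov <- st$v_cov[names(st$v_cov) != covariate]
    st
  }
  trace <- list()
  note <- function(phase, param, covariate, dofv, action) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, param = param, covariate = covariate, delta_ofv = dofv,
      action = action, stringsAsFactors = FALSE)
  }
  base_fit <- refit(struct)
  remaining <- cand
  selected <- cand[0, , drop = FALSE]
  # forward selection
  while (nrow(remaining)) {
    dofv <- numeric(nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      sti <- add_cov(struct, remaining$param[i], remaining$covariate[i])
      fits[[i]] <- refit(sti)
      dofv[i] <- base_fit$ofv - fits[[i]]$ofv
    }
    best <- which.max(dofv)
    if (dofv[best] > cfg$forward_dofv) {
      note("forward", remaining$param[best], remaining$covariate[best],
           dofv[best], "added")
      struct <- add_cov(struct, remaining$param[best],
                        remaining$covariate[best])
      base_fit <- fits[[best]]
      selected <- rbind(selected, remaining[best, , drop = FALSE])
      remaining <- remaining[-best, , drop = FALSE]
    } else {
      for (i in seq_len(nrow(remaining)))
        note("forward", remaining$param[i], remaining$covariate[i], dofv[i],
             "rejected")
      break
    }
  }
  # backward elimination on the forward-selected set
  keep_going <- nrow(selected) > 0
  while (keep_going) {
    keep_going <- FALSE
    for (i in seq_len(nrow(selected))) {
      sti <- drop_cov(struct, selected$param[i], selected$covariate[i])
      fi <- refit(sti)
      dofv <- fi$ofv - base_fit$ofv
      if (dofv <= cfg$backward_dofv) {
        note("backward", selected$param[i], selected$covariate[i], dofv,
             "removed")
        struct <- sti
        base_fit <- fi
        selected <- selected[-i, , drop = FALSE]
        keep_going <- nrow(selected) > 0
        break
      } else {
        note("backward", selected$param[i], selected$covariate[i], dofv,
             "retained")
      }
    }
    if (keep_going == FALSE) break
  }
  structure(list(structure = struct, fit = base_fit,
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(phase = character(), param = character(),
                              covariate = character(),
                              delta_ofv = numeric(), action = character())),
            class = "stepwise_result")
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits, and summarizes each
#' parameter by the median and 2.5/97.5 percentiles over converged
#' replicates. Non-converged replicates are dropped and counted.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param cfg a \code{\link{fit_config}}.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return A list of class \code{popk_bootstrap}: \code{summary}
#'   (parameter, median, ci_lo, ci_hi), \code{replicates} (matrix of
#'   per-replicate estimates), \code{n_failed}.
#' @export
bootstrap_popk <- function(ds, cfg = fit_config(), n_reps = 200L, seed = 1L) {
  stopifnot(n_reps >= 1)
  ids <- unique(ds$ID)
  by_id <- split(seq_len(nrow(ds)), ds$ID)
  cfg$compute_se <- FALSE
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      pick <- sample(ids, length(ids), replace = TRUE)
      parts <- lapply(seq_along(pick), function(j) {
        rows <- ds[by_id[[as.character(pick[j])]], , drop = FALSE]
        rows$ID <- paste0("b", j)
        rows
      })
      bds <- tdm_dataset(do.call(rbind, parts), source = "bootstrap")
      f <- tryCatch(suppressWarnings(fit_popk(bds, cfg)),
                    error = function(e) NULL)
      if (is.null(f) || !f$convergence) NULL else f$estimates
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  mat <- do.call(rbind, reps[ok])
  qs <- apply(mat, 2, stats::quantile, probs = c(0.5, 0.025, 0.975))
  structure(list(
    summary = data.frame(parameter = colnames(mat), median = qs[1, ],
                         ci_lo = qs[2, ], ci_hi = qs[3, ], row.names = NULL),
    replicates = mat, n_failed = sum(!ok)),
    class = "popk_bootstrap")
}
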