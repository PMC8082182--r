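# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

age_band_bounds <- function(band) {
  switch(band,
         "0-3m" = c(0.0164, 0.25),
         "3m-12y" = c(0.25, 12),
         "12y-17y" = c(12, 17),
         "mixed" = c(0.0164, 13.0),
         "adult" = c(18, 80),
         stop("unknown age band: ", band, call. = FALSE))
}

# Compact piecewise-linear median growth tables (age in years). Chosen as a
# light-weight stand-in for full growth charts; swappable via the knots
# arguments of generate_cohort.
default_weight_knots <- function() {
  data.frame(age = c(0, 0.25, 1, 5, 12, 17, 80),
             value = c(3.3, 6, 9.5, 18, 40, 55, 62))
}
default_height_knots <- function() {
  data.frame(age = c(0, 0.25, 1, 5, 12, 17, 80),
             value = c(0.50, 0.60, 0.75, 1.10, 1.50, 1.65, 1.68))
}

#' Virtual-cohort specification
#'
#' @param n number of patients, > 0.
#' @param age_band one of \code{"0-3m"}, \code{"3m-12y"}, \code{"12y-17y"},
#'   \code{"mixed"} (the full pediatric study range, 0.0164-13 years) or
#'   \code{"adult"}.
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n, age_band = "mixed", seed = 1L) {
  if (n <= 0) stop("'n' must be positive", call. = FALSE)
  bounds <- age_band_bounds(age_band)
  structure(list(n = as.integer(n), age_band = age_band,
                 age_min = bounds[1], age_max = bounds[2],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper, max_tries = 1000L) {
  out <- stats::rlnorm(n, meanlog, sdlog)
  for (i in seq_len(max_tries)) {
    bad <- out <= lower | out >= upper
    if (!any(bad)) return(out)
    out[bad] <- stats::rlnorm(sum(bad), meanlog[bad], sdlog)
  }
  stop("unsatisfiable truncation bounds in cohort generation", call. = FALSE)
}

rnorm_trunc <- function(n, mean, sd, lower, upper, max_tries = 1000L) {
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- out < lower | out > upper
    if (!any(bad)) return(out)
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  stop("unsatisfiable truncation bounds in cohort generation", call. = FALSE)
}

#' Generate a virtual patient cohort
#'
#' Ages are drawn log-uniformly within the band (for the \code{"mixed"}
#' pediatric band, 0.0164-13 years, this gives a median near 0.46 years,
#' matching a cohort dominated by neonates and infants). Weight and height
#' follow piecewise-linear median-for-age curves with log-normal scatter
#' (CV 15\% and 4\%), truncated to the plausible study ranges
#' (weight 0.9-55 kg, height 0.3-1.7 m for pediatric bands). Serum
#' creatinine is normal with an age-dependent mean (18 + 2*age umol/L,
#' SD 6), truncated to 9-83 umol/L. Creatinine clearance is derived with
#' \code{\link{creatinine_clearance}}. Deterministic given the seed.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param weight_knots,height_knots optional data.frames (columns \code{age},
#'   \code{value}) overriding the median growth curves.
#' @param clcr_scale passed to \code{\link{creatinine_clearance}}.
#' @return A \code{\link{patient_covariates}} table with \code{spec$n} rows.
#' @export
generate_cohort <- function(spec, weight_knots = default_weight_knots(),
                            height_knots = default_height_knots(),
                            clcr_scale = "normalized") {
  with_seed(spec$seed, {
    n <- spec$n
    age <- exp(stats::runif(n, log(spec$age_min), log(spec$age_max)))
    wt_med <- stats::approx(weight_knots$age, weight_knots$value,
                            xout = age, rule = 2)$y
    wt_lim <- if (spec$age_band == "adult") c(40, 120) else c(0.9, 55.0)
    wt <- rlnorm_trunc(n, log(wt_med), 0.15, wt_lim[1], wt_lim[2])
    ht_med <- stats::approx(height_knots$age, height_knots$value,
                            xout = age, rule = 2)$y
    ht_lim <- if (spec$age_band == "adult") c(1.4, 2.1) else c(0.30, 1.70)
    ht <- rlnorm_trunc(n, log(ht_med), 0.04, ht_lim[1], ht_lim[2])
    scr <- rnorm_trunc(n, 18 + 2 * age, 6, 9, 83)
    sex <- ifelse(stats::runif(n) < 0.5, "M", "F")
    cov <- patient_covariates(age = age, weight = wt, height = ht, scr = scr,
                              sex = sex)
    cov$CLCR <- creatinine_clearance(cov, scale = clcr_scale)
    attr(cov, "spec") <- spec
    cov
  })
}

#' TDM sampling design
#'
#' The routine-care design draws one trough sample shortly before a stated
#' dose (default the fifth) and one peak sample in a window after the end of
#' that dose's infusion. The assay lower limit of quantification defaults to
#' 3.00 mg/L.
#'
#' @param trough_offset h before the indexed dose at which the trough is
#'   drawn (default 0.5).
#' @param peak_window numeric length-2, h after the end of infusion within
#'   which the peak is drawn uniformly (default \code{c(0.5, 1)}).
#' @param dose_index which dose the samples bracket (default 5).
#' @param lloq assay lower limit of quantification (mg/L); set 0 to disable
#'   censoring flags.
#' @return An object of class \code{sampling_design}.
#' @export
sampling_design <- function(trough_offset = 0.5, peak_window = c(0.5, 1),
                            dose_index = 5L, lloq = 3.00) {
  stopifnot(trough_offset > 0, length(peak_window) == 2,
            peak_window[1] <= peak_window[2], dose_index >= 1)
  structure(list(trough_offset = trough_offset, peak_window = peak_window,
                 dose_index = as.integer(dose_index), lloq = lloq),
            class = "sampling_design")
}

#' Simulate TDM observations for a cohort
#'
#' Per subject, draws \eqn{\eta \sim N(0, diag(\omega^2_{CL},
#' \omega^2_V))}, administers \code{design$dose_index} doses of
#' \code{daily_dose_per_kg} scaled to body weight at interval \code{tau},
#' and emits one trough and one peak observation with proportional residual
#' noise \eqn{y = f (1 + \epsilon)}. Observations below the design LLOQ are
#' flagged BLQ (dose and observation rows are always emitted; the exclusion
#' policy is applied at fitting time). Byte-identical under a fixed seed.
#'
#' @param cohort a \code{\link{patient_covariates}} table.
#' @param regimen a \code{\link{dosing_regimen}} built with
#'   \code{daily_dose_per_kg} (per-subject doses are scaled by weight), or
#'   with a fixed \code{dose}.
#' @param p \code{\link{population_parameters}}.
#' @param design a \code{\link{sampling_design}}.
#' @param seed integer RNG seed.
#' @return A \code{\link{tdm_dataset}}; the drawn random effects are stored
#'   in \code{attr(, "eta")} (an \code{n x 2} matrix) for testing.
#' @export
simulate_tdm <- function(cohort, regimen, p = population_parameters(),
                         design = sampling_design(), seed = 1L) {
  with_seed(seed, {
    n <- nrow(cohort)
    eta <- cbind(stats::rnorm(n, 0, sqrt(p$omega2_cl)),
                 stats::rnorm(n, 0, sqrt(p$omega2_v)))
    tau <- regimen$interval
    tinf <- regimen$infusion_duration
    last_dose_t <- (design$dose_index - 1) * tau
    peak_t <- last_dose_t + tinf +
      stats::runif(n, design$peak_window[1], design$peak_window[2])
    trough_t <- rep(last_dose_t - design$trough_offset, n)
    eps <- matrix(stats::rnorm(2 * n, 0, sqrt(p$sigma2_prop)), n, 2)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cov_i <- cohort[i, , drop = FALSE]
      dose_i <- if (!is.null(regimen$daily_dose_per_kg))
        regimen$daily_dose_per_kg * cov_i$WT / (24 / tau) else regimen$dose
      reg_i <- dosing_regimen(dose = dose_i, interval = tau,
                              infusion_duration = tinf,
                              n_doses = design$dose_index)
      cl_i <- clearance(cov_i, eta[i, 1], p)
      v_i <- volume(cov_i, eta[i, 2], p)
      f <- concentration_at_time(cl_i, v_i, reg_i, c(trough_t[i], peak_t[i]))
      dv <- pmax(f * (1 + eps[i, ]), 1e-3)
      dose_rows <- data.frame(
        ID = cov_i$ID, TIME = (seq_len(design$dose_index) - 1) * tau,
        AMT = dose_i, RATE = dose_i / tinf, EVID = 1L, MDV = 1L,
        DV = NA_real_, BLQ = 0L, LLOQ = design$lloq)
      obs_rows <- data.frame(
        ID = cov_i$ID, TIME = c(trough_t[i], peak_t[i]),
        AMT = NA_real_, RATE = NA_real_, EVID = 0L, MDV = 0L,
        DV = dv, BLQ = as.integer(dv < design$lloq), LLOQ = design$lloq)
      sub <- rbind(dose_rows, obs_rows)
      sub$AGE <- cov_i$AGE; sub$WT <- cov_i$WT; sub$HT <- cov_i$HT
      sub$SCR <- cov_i$SCR; sub$CLCR <- cov_i$CLCR; sub$SEX <- cov_i$SEX
      rows[[i]] <- sub
    }
    ds <- tdm_dataset(do.call(rbind, rows), source = "synthetic", seed = seed)
    attr(ds, "eta") <- eta
    ds
  })
}

#' Outcome-generation rates
#'
#' Marginal rates and optional exposure-response slope for
#' \code{\link{simulate_outcomes}}. The default improvement rate (0.926) and
#' MIC distribution (MIC50 = 1, MIC90 in \{1, 2\}) mirror the clinical
#' efficacy level and isolate MIC pattern typical of pediatric Gram-positive
#' cohorts treated with vancomycin.
#'
#' @param improve_rate marginal clinical-improvement probability.
#' @param eradicate_rate marginal microbiological-eradication probability.
#' @param log_odds_slope slope on \code{log2(AUC/MIC)} (0 = no
#'   exposure-response).
#' @param organism_probs named probabilities over organisms.
#' @param site_probs named probabilities over infection sites.
#' @param mic_probs named probabilities over the doubling-dilution MIC grid.
#' @return A list of class \code{outcome_rates}.
#' @export
outcome_rates <- function(improve_rate = 0.926, eradicate_rate = 0.95,
                          log_odds_slope = 0,
                          organism_probs = c(SA = 0.33, CoNS = 0.33,
                                             Enterococcus = 0.20,
                                             Other = 0.14),
                          site_probs = c(Bloodstream = 0.47, Pulmonary = 0.28,
                                         `Urinary tract` = 0.16,
                                         `Central nervous system` = 0.09),
                          mic_probs = c(`0.5` = 0.15, `1` = 0.75,
                                        `2` = 0.10)) {
  stopifnot(improve_rate >= 0, improve_rate <= 1,
            eradicate_rate >= 0, eradicate_rate <= 1)
  structure(list(improve_rate = improve_rate,
                 eradicate_rate = eradicate_rate,
                 log_odds_slope = log_odds_slope,
                 organism_probs = organism_probs, site_probs = site_probs,
                 mic_probs = mic_probs),
            class = "outcome_rates")
}

#' Simulate clinical and microbiological outcome records
#'
#' Bernoulli outcomes at the configured marginal rates, optionally with a
#' log-odds slope on \code{log2(AUC/MIC)} (centered at its median) so that
#' exposure-response power can be studied. Organism, infection site and MIC
#' are drawn from the configured categorical distributions.
#'
#' @param cohort a \code{\link{patient_covariates}} table.
#' @param indices data.frame of per-subject PK/PD indices with at least an
#'   \code{auc24} column (e.g. from \code{\link{map_indices}}), or
#'   \code{NULL} to draw AUC-independent outcomes.
#' @param rates an \code{\link{outcome_rates}} configuration.
#' @param seed integer RNG seed.
#' @return A data.frame with one row per subject: \code{ID},
#'   \code{clinical_improved}, \code{eradicated}, \code{infection_site},
#'   \code{organism}, \code{mic}, \code{auc24}, \code{auc24_over_mic}.
#' @export
simulate_outcomes <- function(cohort, indices = NULL,
                              rates = outcome_rates(), seed = 1L) {
  with_seed(seed, {
    n <- nrow(cohort)
    organism <- sample(names(rates$organism_probs), n, replace = TRUE,
                       prob = rates$organism_probs)
    site <- sample(names(rates$site_probs), n, replace = TRUE,
                   prob = rates$site_probs)
    mic <- as.numeric(sample(names(rates$mic_probs), n, replace = TRUE,
                             prob = rates$mic_probs))
    auc <- if (!is.null(indices)) indices$auc24 else rep(NA_real_, n)
    aucmic <- auc / mic
    lin <- stats::qlogis(rates$improve_rate)
    if (rates$log_odds_slope != 0 && !all(is.na(aucmic))) {
      x <- log2(aucmic)
      lin <- lin + rates$log_odds_slope * (x - stats::median(x, na.rm = TRUE))
    }
    improved <- as.integer(stats::runif(n) < stats::plogis(lin))
    eradicated <- as.integer(stats::runif(n) < rates$eradicate_rate)
    data.frame(ID = cohort$ID, clinical_improved = improved,
               eradicated = eradicated, infection_site = site,
               organism = organism, mic = mic, auc24 = auc,
               auc24_over_mic = aucmic, stringsAsFactors = FALSE)
  })
}
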