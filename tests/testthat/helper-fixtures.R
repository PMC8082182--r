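# Shared fixtures: everything is generated in code at test time.

truth_params <- function() population_parameters()

# deliberately generic starting values, away from the generating truth
generic_init <- function() {
  population_parameters(cl_typ = 2, v_typ = 30, clcr_exp = 0.75,
                        wt_exp_cl = 0.75, age_exp_v = 0.2, wt_exp_v = 0.5,
                        omega2_cl = 0.1, omega2_v = 0.1, sigma2_prop = 0.05)
}

make_tdm <- function(n = 50, seed = 1, lloq = 3, daily = 60, interval = 6,
                     band = "mixed", p = truth_params()) {
  cohort <- generate_cohort(cohort_spec(n, band, seed = seed))
  simulate_tdm(cohort, dosing_regimen(daily_dose_per_kg = daily,
                                      interval = interval),
               p, sampling_design(lloq = lloq), seed = seed + 1000L)
}

# one subject with an arbitrary dosing history and observation times
make_subject <- function(times_obs, dv, doses_t, amt, rate, cov_row,
                         id = "s1") {
  dose_rows <- data.frame(ID = id, TIME = doses_t, AMT = amt, RATE = rate,
                          EVID = 1L, MDV = 1L, DV = NA_real_,
                          BLQ = 0L, LLOQ = 0)
  df <- dose_rows
  if (length(times_obs)) {
    obs_rows <- data.frame(ID = id, TIME = times_obs, AMT = NA_real_,
                           RATE = NA_real_, EVID = 0L, MDV = 0L, DV = dv,
                           BLQ = 0L, LLOQ = 0)
    df <- rbind(dose_rows, obs_rows)
  }
  df$AGE <- cov_row$AGE; df$WT <- cov_row$WT; df$HT <- cov_row$HT
  df$SCR <- cov_row$SCR; df$CLCR <- cov_row$CLCR; df$SEX <- cov_row$SEX
  tdm_dataset(df)
}
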