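test_that("the conditional objective matches an independent transcription of the formula", {
  p <- population_parameters(omega2_cl = 0.2, omega2_v = 0.05,
                             sigma2_prop = 0.06)
  cov <- patient_covariates(age = 2, weight = 12, clcr = 80)
  # dosing: 100 mg over 1 h at 0 and 8 h; observations at 7.5 and 9 h
  ds <- make_subject(times_obs = c(7.5, 9), dv = c(6.1, 14.2),
                     doses_t = c(0, 8), amt = 100, rate = 100, cov_row = cov)
  eta <- c(0.3, -0.1)

  # independent: closed-form concentrations and a literal sum
  cl <- 3.83 * (80 / 90.28)^0.516 * (12 / 58.25)^0.646 * exp(eta[1])
  v <- 44.7 * (2 / 55)^0.33 * (12 / 58.25)^0.349 * exp(eta[2])
  k <- cl / v
  conc1 <- function(t, t0) { # one 1-h infusion of 100 mg/h starting at t0
    if (t <= t0) return(0)
    dt <- t - t0
    if (dt <= 1) (100 / cl) * (1 - exp(-k * dt))
    else (100 / cl) * (1 - exp(-k * 1)) * exp(-k * (dt - 1))
  }
  f <- c(conc1(7.5, 0) + conc1(7.5, 8), conc1(9, 0) + conc1(9, 8))
  y <- c(6.1, 14.2)
  s2 <- 0.06
  expected <- sum((y - f)^2 / (s2 * f^2) + log(s2 * f^2)) +
    eta[1]^2 / 0.2 + eta[2]^2 / 0.05 + log((2 * pi)^2 * 0.2 * 0.05)
  expect_equal(subject_conditional_objective(ds, p, eta), expected,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("inflating a single residual strictly increases the conditional objective", {
  p <- population_parameters()
  cov <- patient_covariates(age = 1, weight = 9, clcr = 100)
  base <- make_subject(c(23.5, 25.2), c(5, 20), (0:4) * 6, 90, 90, cov)
  worse <- make_subject(c(23.5, 25.2), c(5, 35), (0:4) * 6, 90, 90, cov)
  expect_gt(subject_conditional_objective(worse, p, c(0, 0)),
            subject_conditional_objective(base, p, c(0, 0)))
})

test_that("a single-subject OFV equals the conditional objective plus the Laplace curvature term", {
  p <- population_parameters()
  cov <- patient_covariates(age = 3, weight = 14, clcr = 110)
  ds <- make_subject(c(23.5, 25.2, 30, 40), c(7.2, 21.5, 10.1, 4.4),
                     (0:6) * 8, 140, 140, cov)
  g <- function(eta) subject_conditional_objective(ds, p, eta)
  opt <- optim(c(0, 0), g, method = "BFGS",
               control = list(reltol = 1e-14))
  h <- 1e-4 # independent central-difference Hessian of the objective
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- replace(numeric(2), i, h); ej <- replace(numeric(2), j, h)
    H[i, j] <- (g(opt$par + ei + ej) - g(opt$par + ei - ej) -
                  g(opt$par - ei + ej) + g(opt$par - ei - ej)) / (4 * h^2)
  }
  expected <- opt$value + 4 * log(2 * pi) - 2 * log(2 * pi) +
    log(det(H) / 4)
  expect_equal(as.numeric(foce_objective(ds, p)), expected, tolerance = 1e-5)
})

test_that("the marginal objective is invariant to subject order", {
  p <- truth_params()
  ds <- make_tdm(n = 12, seed = 44, lloq = 0)
  ids <- unique(ds$ID)
  perm <- sample(ids)
  rows <- do.call(rbind, lapply(perm, function(i)
    as.data.frame(ds[ds$ID == i, ])))
  ds2 <- tdm_dataset(rows)
  expect_equal(as.numeric(foce_objective(ds, p)),
               as.numeric(foce_objective(ds2, p)), tolerance = 1e-8)
})

test_that("with near-zero variability the fixed effects are recovered almost exactly", {
  p_tiny <- population_parameters(omega2_cl = 1e-6, omega2_v = 1e-6,
                                  sigma2_prop = 1e-6)
  ds <- make_tdm(n = 30, seed = 17, lloq = 0, p = p_tiny)
  cfg <- fit_config(
    init = population_parameters(cl_typ = 3, v_typ = 30, clcr_exp = 0.4,
                                 wt_exp_cl = 0.5, age_exp_v = 0.2,
                                 wt_exp_v = 0.2, omega2_cl = 1e-6,
                                 omega2_v = 1e-6, sigma2_prop = 1e-6),
    estimate = c("log_cl_typ", "cl_CLCR_exp", "cl_WT_exp", "log_v_typ",
                 "v_AGE_exp", "v_WT_exp"),
    compute_se = FALSE)
  f <- fit_popk(ds, cfg)
  expect_true(f$convergence)
  expect_lt(f$ofv, f$ofv_initial) # optimizer only ever improves the OFV
  expect_lt(abs(f$estimates["cl_typ"] / 3.83 - 1), 0.005)
  expect_lt(abs(f$estimates["cl_CLCR_exp"] - 0.516), 0.005)
  expect_lt(abs(f$estimates["cl_WT_exp"] - 0.646), 0.005)
  # age and weight are nearly collinear across a pediatric cohort, so the
  # V-side parameters sit on a flat ridge; the typical value still pins
  # down to within a couple percent
  expect_lt(abs(f$estimates["v_typ"] / 44.7 - 1), 0.02)
  expect_lt(abs(f$estimates["v_AGE_exp"] - 0.33), 0.02)
  expect_lt(abs(f$estimates["v_WT_exp"] - 0.349), 0.02)
})

test_that("standard errors from the outer Hessian are finite and scale-consistent", {
  ds <- make_tdm(n = 80, seed = 29, lloq = 0)
  cfg <- fit_config(init = generic_init(),
                    estimate = c("log_cl_typ", "cl_CLCR_exp", "cl_WT_exp",
                                 "log_v_typ", "log_omega2_cl", "log_sigma2"),
                    compute_se = TRUE)
  f <- fit_popk(ds, cfg)
  tab <- f$table[f$table$estimated, ]
  expect_true(all(is.finite(tab$se)))
  expect_true(all(tab$se > 0))
  expect_true(all(tab$rse_pct > 0 & tab$rse_pct < 100))
  expect_true(all(tab$ci_lo < tab$estimate & tab$estimate < tab$ci_hi))
})

test_that("refitting self-simulated cohorts recovers the generating parameters on average", {
  p <- truth_params()
  init <- generic_init()
  reps <- 8
  est <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("th1", "th3", "th4", "om2")))
  for (r in seq_len(reps)) {
    ds <- make_tdm(n = 100, seed = 500 + r, lloq = 0)
    f <- fit_popk(ds, fit_config(init = init, compute_se = FALSE))
    est[r, ] <- f$estimates[c("cl_typ", "cl_CLCR_exp", "cl_WT_exp",
                              "omega2_cl")]
  }
  expect_lt(abs(mean(est[, "th1"]) / 3.83 - 1), 0.10)
  expect_lt(abs(mean(est[, "th3"]) - 0.516), 0.15)
  expect_lt(abs(mean(est[, "th4"]) - 0.646), 0.15)
  expect_lt(abs(mean(est[, "om2"]) / 0.204 - 1), 0.40)
})

test_that("stepwise selection finds a genuine weight effect on clearance", {
  # generate with a weight effect on CL only; no covariates on V
  p_w <- population_parameters(clcr_exp = 0, wt_exp_cl = 0.646,
                               age_exp_v = 0, wt_exp_v = 0,
                               omega2_v = 0.02)
  ds <- make_tdm(n = 200, seed = 61, lloq = 0, p = p_w)
  cfg <- fit_config(init = population_parameters(
    cl_typ = 1, v_typ = 10, omega2_cl = 0.1, omega2_v = 0.1,
    sigma2_prop = 0.05),
    model = pk_structure(cl_cov = c(), v_cov = c()), compute_se = FALSE)
  res <- stepwise_covariates(ds, data.frame(param = "cl", covariate = "WT"),
                             cfg)
  expect_true("WT" %in% names(res$structure$cl_cov))
  expect_true(any(res$trace$action == "added"))
  expect_gt(res$trace$delta_ofv[res$trace$action == "added"][1], 6.63)
})

test_that("stepwise with no candidates returns the base model unchanged", {
  ds <- make_tdm(n = 25, seed = 71, lloq = 0)
  cfg <- fit_config(init = generic_init(),
                    model = pk_structure(cl_cov = c(), v_cov = c()),
                    compute_se = FALSE)
  res <- stepwise_covariates(ds, data.frame(param = character(),
                                            covariate = character()), cfg)
  expect_length(res$structure$cl_cov, 0)
  expect_identical(nrow(res$trace), 0L)
})

test_that("a pure-noise candidate is rarely selected at the 3.84 threshold", {
  p0 <- population_parameters(clcr_exp = 0, wt_exp_cl = 0, age_exp_v = 0,
                              wt_exp_v = 0, cl_typ = 1.2, v_typ = 6,
                              omega2_cl = 0.15, omega2_v = 0.03)
  reps <- 25
  chosen <- logical(reps)
  for (r in seq_len(reps)) {
    ds <- make_tdm(n = 40, seed = 900 + r, lloq = 0, p = p0)
    df <- as.data.frame(ds)
    noise <- withr::with_seed(3000 + r,
                              stats::setNames(runif(40, 0.5, 2),
                                              unique(df$ID)))
    df$NOISE <- noise[as.character(df$ID)]
    dsn <- tdm_dataset(df)
    cfg <- fit_config(init = population_parameters(
      cl_typ = 1, v_typ = 5, omega2_cl = 0.1, omega2_v = 0.05,
      sigma2_prop = 0.06),
      model = pk_structure(cl_cov = c(), v_cov = c()), compute_se = FALSE)
    res <- suppressWarnings(
      stepwise_covariates(dsn, data.frame(param = "cl",
                                          covariate = "NOISE"), cfg))
    chosen[r] <- "NOISE" %in% names(res$structure$cl_cov)
  }
  # nominal type-I rate is ~5%; require clearly below 10% allowing
  # binomial noise at 25 replicates
  expect_lte(sum(chosen), 4)
})

test_that("bootstrap percentiles match a direct computation and degenerate cases behave", {
  ds <- make_tdm(n = 30, seed = 81, lloq = 0)
  cfg <- fit_config(init = generic_init(),
                    estimate = c("log_cl_typ", "log_v_typ", "log_omega2_cl",
                                 "log_sigma2"),
                    compute_se = FALSE)
  bs <- bootstrap_popk(ds, cfg, n_reps = 8, seed = 5)
  expect_identical(bs$n_failed + nrow(bs$replicates), 8L)
  # percentile oracle: direct quantile on the stored replicate matrix
  for (j in seq_len(ncol(bs$replicates))) {
    expect_equal(bs$summary$median[j],
                 unname(stats::quantile(bs$replicates[, j], 0.5)))
    expect_equal(bs$summary$ci_lo[j],
                 unname(stats::quantile(bs$replicates[, j], 0.025)))
    expect_equal(bs$summary$ci_hi[j],
                 unname(stats::quantile(bs$replicates[, j], 0.975)))
  }
  one <- bootstrap_popk(ds, cfg, n_reps = 1, seed = 6)
  expect_equal(one$summary$median, unname(one$replicates[1, ]))

  # the bootstrap medians track the point estimate on well-behaved data
  f <- fit_popk(ds, cfg)
  expect_lt(abs(bs$summary$median[bs$summary$parameter == "cl_typ"] /
                  f$estimates["cl_typ"] - 1), 0.25)
})
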