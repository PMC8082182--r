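test_that("clearance and volume reproduce their typical values at the reference covariates", {
  p <- population_parameters()
  ref <- patient_covariates(age = 55, weight = 58.25, clcr = 90.28)
  expect_equal(clearance(ref, 0, p), 3.83)
  expect_equal(volume(ref, 0, p), 44.7)
  # eta enters multiplicatively on the exponential scale
  expect_equal(clearance(ref, 0.5, p), 3.83 * exp(0.5))
  expect_equal(volume(ref, -0.2, p), 44.7 * exp(-0.2))
})

test_that("covariate power laws match direct arithmetic", {
  p <- population_parameters()
  half_clcr <- patient_covariates(age = 55, weight = 58.25, clcr = 45.14)
  expect_equal(clearance(half_clcr, 0, p),
               3.83 * exp(0.516 * log(45.14 / 90.28)), tolerance = 1e-12)
  infant <- patient_covariates(age = 1, weight = 10, clcr = 90.28)
  expect_equal(volume(infant, 0, p),
               44.7 * exp(0.33 * log(1 / 55) + 0.349 * log(10 / 58.25)),
               tolerance = 1e-12)
})

test_that("clearance is increasing in CLCr and weight, volume in age and weight", {
  p <- population_parameters()
  set.seed(42)
  for (i in 1:25) {
    clcr <- runif(1, 10, 150); wt <- runif(1, 1, 60); age <- runif(1, 0.1, 17)
    a <- patient_covariates(age = age, weight = wt, clcr = clcr)
    b <- patient_covariates(age = age, weight = wt, clcr = clcr * 1.2)
    c_ <- patient_covariates(age = age, weight = wt * 1.2, clcr = clcr)
    d <- patient_covariates(age = age * 1.2, weight = wt, clcr = clcr)
    expect_gt(clearance(b, 0, p), clearance(a, 0, p))
    expect_gt(clearance(c_, 0, p), clearance(a, 0, p))
    expect_gt(volume(d, 0, p), volume(a, 0, p))
    expect_gt(volume(c_, 0, p), volume(a, 0, p))
  }
})

test_that("missing or degenerate covariates raise errors naming the field", {
  p <- population_parameters()
  no_clcr <- patient_covariates(age = 2, weight = 12)
  expect_error(clearance(no_clcr, 0, p), "CLCR")
  expect_error(volume(data.frame(AGE = 0, WT = 10), 0, p), "AGE")
  expect_error(patient_covariates(age = 1, weight = -3), "WT")
  expect_error(patient_covariates(age = 1, weight = 5, scr = -1), "SCR")
})

test_that("creatinine clearance passthrough, reciprocal scaling and Schwartz chain", {
  has <- patient_covariates(age = 3, weight = 14, clcr = 77)
  expect_identical(creatinine_clearance(has), 77)

  a <- patient_covariates(age = 4, weight = 16, height = 1.0, scr = 20)
  b <- patient_covariates(age = 4, weight = 16, height = 1.0, scr = 40)
  expect_equal(creatinine_clearance(b), creatinine_clearance(a) / 2)

  # hand-computed unit-conversion chain: 20 umol/L = 20/88.42 mg/dL,
  # bedside Schwartz = 0.413 * 100 cm / (20/88.42)
  expect_equal(creatinine_clearance(a), 0.413 * 100 / (20 / 88.42),
               tolerance = 1e-12)
  # absolute scale applies the Mosteller BSA / 1.73 factor
  bsa <- sqrt(100 * 16 / 3600)
  expect_equal(creatinine_clearance(a, scale = "absolute"),
               0.413 * 100 / (20 / 88.42) * bsa / 1.73, tolerance = 1e-12)
  # adult branch: Cockcroft-Gault with the same unit conversion
  ad <- patient_covariates(age = 40, weight = 70, scr = 80, sex = "M")
  expect_equal(creatinine_clearance(ad),
               (140 - 40) * 70 / (72 * 80 / 88.42), tolerance = 1e-12)
  ped_no_ht <- patient_covariates(age = 4, weight = 16, scr = 20)
  expect_error(creatinine_clearance(ped_no_ht), "HT")
})

test_that("intermittent-infusion concentrations match an independent ODE solution", {
  skip_if_not_installed("deSolve")
  set.seed(7)
  for (i in 1:4) {
    cl <- runif(1, 0.3, 5); v <- runif(1, 2, 40)
    reg <- dosing_regimen(dose = runif(1, 50, 500), interval = sample(c(6, 8, 12), 1),
                          infusion_duration = 1, n_doses = 5)
    rate <- reg$dose / reg$infusion_duration
    deriv <- function(t, y, parms) {
      tin <- t %% reg$interval
      infusing <- t < reg$n_doses * reg$interval & tin < reg$infusion_duration
      list(ifelse(infusing, rate, 0) - (cl / v) * y)
    }
    tt <- sort(c(runif(20, 0, 40), 4 * reg$interval + 0.75))
    ode <- deSolve::lsoda(c(A = 0), c(0, tt), deriv, NULL,
                          rtol = 1e-10, atol = 1e-10, hmax = 0.05)
    expect_equal(concentration_at_time(cl, v, reg, tt), ode[-1, "A"] / v,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  reg <- dosing_regimen(dose = 100, interval = 8, n_doses = 1)
  expect_equal(concentration_at_time(1, 10, reg, 0), 0)
  expect_lt(concentration_at_time(1, 10, reg, 500), 1e-12)
})

test_that("steady-state peak/trough agree with brute-force superposition", {
  set.seed(11)
  for (i in 1:5) {
    cl <- runif(1, 0.3, 5); v <- runif(1, 2, 40)
    tau <- sample(c(6, 8, 12), 1)
    reg <- dosing_regimen(dose = runif(1, 50, 500), interval = tau,
                          infusion_duration = 1, n_doses = 200)
    ss <- steady_state_indices(cl, v, reg)
    t_peak <- 199 * tau + reg$infusion_duration
    t_trough <- 200 * tau
    expect_equal(ss$cmax_ss, concentration_at_time(cl, v, reg, t_peak),
                 tolerance = 1e-6)
    expect_equal(ss$cmin_ss, concentration_at_time(cl, v, reg, t_trough),
                 tolerance = 1e-6)
    # algebraic trough/peak identity
    expect_equal(ss$cmin_ss / ss$cmax_ss,
                 exp(-(cl / v) * (tau - reg$infusion_duration)),
                 tolerance = 1e-12)
  }
  # tau -> infinity limit: accumulation factor collapses to a single dose
  reg1 <- dosing_regimen(dose = 200, interval = 1e5, infusion_duration = 1,
                         n_doses = 1)
  ss1 <- steady_state_indices(1.5, 15, reg1)
  expect_equal(ss1$cmax_ss, concentration_at_time(1.5, 15, reg1, 1),
               tolerance = 1e-9)
})

test_that("daily AUC equals the numerical integral of the steady-state profile", {
  expect_equal(auc24_ss(0, 3.83), 0)
  expect_equal(auc24_ss(2000, 3.83), 2000 / 3.83)
  set.seed(3)
  for (i in 1:3) {
    cl <- runif(1, 0.5, 4); v <- runif(1, 3, 30)
    tau <- sample(c(6, 8, 12), 1)
    dose <- runif(1, 50, 400)
    n_dose <- ceiling((10 * log(2) / (cl / v) * 3 + 48) / tau) + 10
    reg <- dosing_regimen(dose = dose, interval = tau, infusion_duration = 1,
                          n_doses = n_dose)
    t0 <- (n_dose - ceiling(24 / tau) - 1) * tau # a steady-state day
    tt <- seq(t0, t0 + 24, by = 0.002)
    cc <- concentration_at_time(cl, v, reg, tt)
    trapz <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
    expect_equal(auc24_ss(dose * 24 / tau, cl), trapz, tolerance = 1e-4)
  }
})

test_that("model yields a physiologically finite volume for a 3 kg neonate", {
  p <- population_parameters()
  neo <- patient_covariates(age = 0.02, weight = 3, clcr = 20)
  v <- volume(neo, 0, p)
  expect_true(is.finite(v) && v > 0.2 && v < 3)
})
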