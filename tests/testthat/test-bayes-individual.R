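test_that("MAP with no observations returns the prior mode", {
  p <- population_parameters()
  cov <- patient_covariates(age = 1, weight = 8, clcr = 60)
  doses_only <- make_subject(numeric(0), numeric(0), (0:4) * 6, 80, 80, cov)
  m <- map_eta(doses_only, p)
  expect_identical(c(m$eta_cl, m$eta_v), c(0, 0))
  expect_identical(m$n_obs, 0L)
})

test_that("observations generated at the population prediction give eta near zero", {
  # the interaction term ln(sigma2 f(eta)^2) shifts the conditional mode
  # away from zero by O(sigma2); the shift must vanish with sigma2
  cov <- patient_covariates(age = 2, weight = 11, clcr = 95)
  reg <- dosing_regimen(dose = 110, interval = 6, n_doses = 5)
  tt <- c(23.5, 25.2)
  p <- population_parameters()
  f <- concentration_at_time(clearance(cov, 0, p), volume(cov, 0, p),
                             reg, tt)
  ds <- make_subject(tt, f, (0:4) * 6, 110, 110, cov)
  m <- map_eta(ds, p)
  expect_lt(abs(m$eta_cl), 0.1)
  expect_lt(abs(m$eta_v), 0.1)
  expect_true(all(eigen(m$hessian)$values > 0))

  p_small <- population_parameters(sigma2_prop = 1e-6)
  m2 <- map_eta(ds, p_small)
  expect_lt(abs(m2$eta_cl), 1e-4)
  expect_lt(abs(m2$eta_v), 1e-4)
})

test_that("rich data recovers the true eta and agrees with an exhaustive grid search", {
  # a weaker V prior and tighter assay noise keep the posterior mode close
  # to the generating eta, so truth recovery is a meaningful check
  p <- population_parameters(omega2_v = 0.2, sigma2_prop = 0.02^2)
  cov <- patient_covariates(age = 4, weight = 17, clcr = 120)
  eta_true <- c(0.35, -0.15)
  cl <- clearance(cov, eta_true[1], p); v <- volume(cov, eta_true[2], p)
  reg <- dosing_regimen(dose = 170, interval = 8, n_doses = 4)
  tt <- seq(24.5, 32, length.out = 12)
  f <- concentration_at_time(cl, v, reg, tt)
  y <- f * (1 + withr::with_seed(5, rnorm(12, 0, 0.02)))
  ds <- make_subject(tt, y, (0:3) * 8, 170, 170, cov)
  m <- map_eta(ds, p)
  expect_lt(abs(m$eta_cl - eta_true[1]), 0.05)
  expect_lt(abs(m$eta_v - eta_true[2]), 0.05)

  # independent oracle: closed-form concentrations + literal objective,
  # minimized by coarse-to-fine exhaustive grid at 0.001 resolution
  obj_grid <- function(e1, e2) {
    cl_i <- clearance(cov, 0, p) * exp(e1)
    v_i <- volume(cov, 0, p) * exp(e2)
    k <- cl_i / v_i
    fi <- 0
    for (t0 in (0:3) * 8) {
      dt <- tt - t0
      up <- pmin(pmax(dt, 0), 1)
      fi <- fi + (170 / cl_i) * (1 - exp(-k * up)) *
        exp(-k * pmax(dt - 1, 0))
    }
    sum((y - fi)^2 / (p$sigma2_prop * fi^2) + log(p$sigma2_prop * fi^2)) +
      e1^2 / p$omega2_cl + e2^2 / p$omega2_v +
      log((2 * pi)^2 * p$omega2_cl * p$omega2_v)
  }
  coarse <- expand.grid(e1 = seq(-1, 1, by = 0.01),
                        e2 = seq(-0.6, 0.6, by = 0.01))
  gv <- mapply(obj_grid, coarse$e1, coarse$e2)
  c0 <- coarse[which.min(gv), ]
  fine <- expand.grid(e1 = seq(c0$e1 - 0.02, c0$e1 + 0.02, by = 0.001),
                      e2 = seq(c0$e2 - 0.02, c0$e2 + 0.02, by = 0.001))
  gv2 <- mapply(obj_grid, fine$e1, fine$e2)
  best <- fine[which.min(gv2), ]
  expect_lt(abs(m$eta_cl - best$e1), 0.002)
  expect_lt(abs(m$eta_v - best$e2), 0.002)
})

test_that("the MAP estimate shrinks toward the prior as residual variance grows", {
  cov <- patient_covariates(age = 2, weight = 11, clcr = 95)
  reg <- dosing_regimen(dose = 110, interval = 6, n_doses = 5)
  p0 <- population_parameters()
  cl <- clearance(cov, 0.5, p0); v <- volume(cov, 0.2, p0)
  tt <- seq(24.5, 29, length.out = 8)
  f <- concentration_at_time(cl, v, reg, tt)
  ds <- make_subject(tt, f, (0:4) * 6, 110, 110, cov)
  # as the residual variance grows the data are downweighted and the
  # mode is pulled away from the data-reproducing eta (0.5, 0.2), toward
  # the prior/interaction-term compromise
  dist <- sapply(c(0.005, 0.02, 0.0749, 0.3), function(s2) {
    m <- map_eta(ds, population_parameters(sigma2_prop = s2))
    sqrt((m$eta_cl - 0.5)^2 + (m$eta_v - 0.2)^2)
  })
  expect_true(all(diff(dist) > 0))
  # and in the small-noise limit the mode reproduces the data exactly
  expect_lt(dist[1], 0.05)
})

test_that("for one observation the mode lies between prior mode and the data-only solution", {
  # pin eta_v with a tight prior so the problem is effectively scalar
  p <- population_parameters(omega2_v = 1e-8)
  cov <- patient_covariates(age = 2, weight = 11, clcr = 95)
  reg <- dosing_regimen(dose = 110, interval = 6, n_doses = 5)
  cl0 <- clearance(cov, 0, p); v0 <- volume(cov, 0, p)
  for (eta_gen in c(-0.6, 0.4)) {
    f1 <- concentration_at_time(cl0 * exp(eta_gen), v0, reg, 25.2)
    ds <- make_subject(25.2, f1, (0:4) * 6, 110, 110, cov)
    m <- map_eta(ds, p)
    # data-only solution: the eta_cl that reproduces the observation exactly
    ls <- uniroot(function(e)
      concentration_at_time(cl0 * exp(e), v0, reg, 25.2) - f1,
      c(-2, 2), tol = 1e-12)$root
    expect_true(m$eta_cl > min(0, ls) - 1e-6 &&
                  m$eta_cl < max(0, ls) + 1e-6)
  }
})

test_that("derived indices compose the model chain and obey MIC identities", {
  p <- population_parameters()
  cov <- patient_covariates(age = 3, weight = 14, clcr = 100)
  reg <- dosing_regimen(dose = 140, interval = 8, infusion_duration = 1)
  eta <- c(0.2, -0.1)
  di <- derive_indices(cov, eta, p, reg, mic = 1)
  expect_equal(di$auc24_over_mic, di$auc24)
  di2 <- derive_indices(cov, eta, p, reg, mic = 2)
  expect_equal(di2$auc24_over_mic, di$auc24 / 2)

  # step-by-step hand evaluation of the full chain
  cl_i <- 3.83 * (100 / 90.28)^0.516 * (14 / 58.25)^0.646 * exp(0.2)
  v_i <- 44.7 * (3 / 55)^0.33 * (14 / 58.25)^0.349 * exp(-0.1)
  k <- cl_i / v_i
  cmax <- (140 / 1 / cl_i) * (1 - exp(-k * 1)) / (1 - exp(-k * 8))
  cmin <- cmax * exp(-k * 7)
  expect_equal(di$cl_i, cl_i, tolerance = 1e-12)
  expect_equal(di$v_i, v_i, tolerance = 1e-12)
  expect_equal(di$cmax_ss, cmax, tolerance = 1e-12)
  expect_equal(di$cmin_ss, cmin, tolerance = 1e-12)
  expect_equal(di$auc24, 140 * 3 / cl_i, tolerance = 1e-12)
  expect_lt(di$cmin_ss, di$cmax_ss)
  expect_error(derive_indices(cov, eta, p, reg, mic = 0), "mic")
})

test_that("the per-subject index table runs end to end on simulated TDM data", {
  ds <- make_tdm(n = 15, seed = 33)
  tab <- map_indices(ds, truth_params(), mic = 1)
  expect_identical(nrow(tab), 15L)
  expect_true(all(tab$cl_i > 0 & tab$v_i > 0))
  expect_true(all(tab$cmin_ss < tab$cmax_ss))
  expect_equal(tab$auc24_over_mic, tab$auc24)
  # MAP eta correlate with the generating eta across subjects
  eta_true <- attr(ds, "eta")
  expect_gt(cor(tab$eta_cl, eta_true[, 1]), 0.6)
})
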