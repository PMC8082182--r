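# Internal machinery for the nonlinear mixed-effects (FOCE-type) objective.
#
# The marginal -2 log-likelihood is approximated subject-by-subject by the
# Laplace method with interaction: the conditional objective
#   g_i(eta) = sum_j [ (y_j - f_j)^2 / (sigma2 f_j^2) + log(sigma2 f_j^2) ]
#              + eta' Omega^-1 eta + log|2 pi Omega|
# is minimized over eta (inner problem), and
#   OFV_i = g_i(eta_hat) + n_i log(2 pi) - 2 log(2 pi) + log det(H_i / 2),
# with H_i the Hessian of g_i at the mode. The residual variance is
# evaluated at the conditional prediction f(eta), which is the
# "with interaction" form. The inner problem is solved for all subjects
# simultaneously by a damped Newton iteration on a finite-difference
# 3x3 stencil (eta is 2-dimensional).

#' Covariate structure of the PK model
#'
#' Describes which covariates enter clearance and volume as normalized
#' power laws. References \code{NA} are replaced by the sample median at
#' fitting time.
#'
#' @param cl_cov named numeric vector of reference values for covariates on
#'   CL (names are dataset columns), e.g. \code{c(CLCR = 90.28, WT = 58.25)}.
#' @param v_cov named numeric vector for covariates on V.
#' @return An object of class \code{pk_structure}.
#' @export
pk_structure <- function(cl_cov = c(CLCR = 90.28, WT = 58.25),
                         v_cov = c(AGE = 55, WT = 58.25)) {
  structure(list(cl_cov = cl_cov, v_cov = v_cov), class = "pk_structure")
}

is_canonical_structure <- function(st) {
  identical(names(st$cl_cov), c("CLCR", "WT")) &&
    identical(names(st$v_cov), c("AGE", "WT"))
}

# Flatten a tdm_dataset into the index structures the objective needs.
prepare_nlme <- function(ds, struct = pk_structure(), include_blq = FALSE) {
  ids <- unique(ds$ID)
  n_subj <- length(ids)
  subj_of <- match(ds$ID, ids)
  cov <- ds[!duplicated(ds$ID), , drop = FALSE]

  cov_matrix <- function(spec) {
    if (length(spec) == 0)
      return(matrix(0, n_subj, 0))
    X <- matrix(0, n_subj, length(spec),
                dimnames = list(NULL, names(spec)))
    refs <- spec
    for (j in seq_along(spec)) {
      nm <- names(spec)[j]
      val <- cov[[nm]]
      if (is.null(val) || any(is.na(val)))
        stop("covariate '", nm, "' missing for structure", call. = FALSE)
      if (is.na(refs[j])) refs[j] <- stats::median(val)
      X[, j] <- log(val / refs[j])
    }
    attr(X, "refs") <- refs
    X
  }
  Xcl <- cov_matrix(struct$cl_cov)
  Xv <- cov_matrix(struct$v_cov)

  is_obs <- ds$EVID == 0 & ds$MDV == 0
  blq <- ds$BLQ == 1
  use <- is_obs & (include_blq | !blq)
  obs_subj <- subj_of[use]
  obs_y <- ds$DV[use]
  if (include_blq) {
    obs_blq <- blq[use]
    obs_y[obs_blq] <- (ds$LLOQ[use])[obs_blq] / 2
  }
  n_obs <- length(obs_y)
  obs_time <- ds$TIME[use]
  n_obs_subj <- tabulate(obs_subj, n_subj)

  # dose-observation pair expansion (within subject, dose before observation)
  is_dose <- ds$EVID == 1
  d_subj <- subj_of[is_dose]
  d_time <- ds$TIME[is_dose]
  d_amt <- ds$AMT[is_dose]
  d_rate <- ds$RATE[is_dose]
  if (any(is.na(d_rate) | d_rate <= 0))
    stop("dose records must carry a positive RATE (mg/h)", call. = FALSE)
  d_dur <- d_amt / d_rate
  dose_idx <- split(seq_along(d_subj), d_subj)

  pair_obs <- pair_u <- pair_w <- pair_rate <- pair_subj <- vector("list", n_obs)
  for (o in seq_len(n_obs)) {
    dd <- dose_idx[[as.character(obs_subj[o])]]
    if (is.null(dd)) next
    dt <- obs_time[o] - d_time[dd]
    keep <- dt > 0
    dd <- dd[keep]; dt <- dt[keep]
    pair_obs[[o]] <- rep.int(o, length(dd))
    pair_subj[[o]] <- rep.int(obs_subj[o], length(dd))
    pair_u[[o]] <- pmin(dt, d_dur[dd])
    pair_w[[o]] <- pmax(dt - d_dur[dd], 0)
    pair_rate[[o]] <- d_rate[dd]
  }
  list(ids = ids, n_subj = n_subj, Xcl = Xcl, Xv = Xv,
       obs_subj = obs_subj, obs_y = obs_y, n_obs = n_obs,
       n_obs_subj = n_obs_subj,
       pair_obs = unlist(pair_obs), pair_subj = unlist(pair_subj),
       pair_u = unlist(pair_u), pair_w = unlist(pair_w),
       pair_rate = unlist(pair_rate),
       n_blq_excluded = sum(is_obs & blq & !include_blq),
       cov = cov)
}

# Predicted concentrations for all retained observations given per-subject
# log CL and log V.
predict_conc <- function(prep, log_cl, log_v) {
  cl <- exp(log_cl)
  k <- exp(log_cl - log_v)
  s <- prep$pair_subj
  contrib <- (prep$pair_rate / cl[s]) * (-expm1(-k[s] * prep$pair_u)) *
    exp(-k[s] * prep$pair_w)
  f <- numeric(prep$n_obs)
  sums <- rowsum(contrib, prep$pair_obs, reorder = FALSE)
  f[as.integer(rownames(sums))] <- sums[, 1]
  f
}

# K-fold tiled copy of the pair/observation index structures, so that the
# conditional objective can be evaluated at K eta-offsets for every subject
# in a single vectorized pass (used for the inner Newton stencil).
make_stack <- function(prep, K) {
  n <- prep$n_subj
  m <- prep$n_obs
  np <- length(prep$pair_obs)
  off_s <- rep(seq_len(K) - 1L, each = np) * n
  off_o <- rep(seq_len(K) - 1L, each = np) * m
  list(K = K, n = n, m = m,
       pair_subj = rep.int(prep$pair_subj, K) + off_s,
       pair_obs = rep.int(prep$pair_obs, K) + off_o,
       pair_u = rep.int(prep$pair_u, K),
       pair_w = rep.int(prep$pair_w, K),
       pair_rate = rep.int(prep$pair_rate, K),
       obs_subj = rep.int(prep$obs_subj, K) +
         rep(seq_len(K) - 1L, each = m) * n,
       obs_y = rep.int(prep$obs_y, K))
}

# Conditional objective at K offsets per subject; returns an n x K matrix.
g_stack <- function(st, base_lcl, base_lv, omega2, sigma2, eta, offsets) {
  K <- st$K
  n <- st$n
  e1 <- rep(eta[, 1], K) + rep(offsets[, 1], each = n)
  e2 <- rep(eta[, 2], K) + rep(offsets[, 2], each = n)
  lcl <- rep(base_lcl, K) + e1
  lv <- rep(base_lv, K) + e2
  cl <- exp(lcl)
  k <- exp(lcl - lv)
  s <- st$pair_subj
  contrib <- (st$pair_rate / cl[s]) * (-expm1(-k[s] * st$pair_u)) *
    exp(-k[s] * st$pair_w)
  f <- numeric(st$m * K)
  sums <- rowsum(contrib, st$pair_obs, reorder = FALSE)
  f[as.integer(rownames(sums))] <- sums[, 1]
  # deep-underflow predictions are floored, not rejected: the likelihood
  # stays finite and steeply repels the optimizer from such regions
  f <- pmax(f, 1e-12)
  r <- (st$obs_y - f)^2 / (sigma2 * f^2) + log(sigma2 * f^2)
  res <- numeric(n * K)
  sums <- rowsum(r, st$obs_subj, reorder = FALSE)
  res[as.integer(rownames(sums))] <- sums[, 1]
  g <- res + e1^2 / omega2[1] + e2^2 / omega2[2] +
    log((2 * pi)^2 * omega2[1] * omega2[2])
  matrix(g, n, K)
}

# Conditional objective g_i for every subject at the given eta (n x 2).
g_all <- function(prep, base_lcl, base_lv, omega2, sigma2, eta) {
  f <- pmax(predict_conc(prep, base_lcl + eta[, 1], base_lv + eta[, 2]),
            1e-12)
  r <- (prep$obs_y - f)^2 / (sigma2 * f^2) + log(sigma2 * f^2)
  res <- numeric(prep$n_subj)
  sums <- rowsum(r, prep$obs_subj, reorder = FALSE)
  res[as.integer(rownames(sums))] <- sums[, 1]
  res + eta[, 1]^2 / omega2[1] + eta[, 2]^2 / omega2[2] +
    log((2 * pi)^2 * omega2[1] * omega2[2])
}

# Damped Newton on a finite-difference stencil, vectorized across subjects.
# Returns the per-subject mode, objective value and Hessian entries.
# When gfun_multi is supplied the whole 9-point stencil is evaluated in a
# single stacked pass.
inner_newton <- function(gfun, eta, max_iter = 25L, tol = 1e-7, h = 1e-4,
                         gfun_multi = NULL) {
  n <- nrow(eta)
  offsets <- rbind(c(0, 0), c(h, 0), c(-h, 0), c(0, h), c(0, -h),
                   c(h, h), c(h, -h), c(-h, h), c(-h, -h))
  g0 <- gfun(eta)
  for (it in seq_len(max_iter)) {
    if (!is.null(gfun_multi)) {
      G <- gfun_multi(eta, offsets)
      g0 <- G[, 1]
      gp0 <- G[, 2]; gm0 <- G[, 3]; g0p <- G[, 4]; g0m <- G[, 5]
      gpp <- G[, 6]; gpm <- G[, 7]; gmp <- G[, 8]; gmm <- G[, 9]
    } else {
      e <- function(d1, d2) gfun(cbind(eta[, 1] + d1, eta[, 2] + d2))
      gp0 <- e(h, 0); gm0 <- e(-h, 0)
      g0p <- e(0, h); g0m <- e(0, -h)
      gpp <- e(h, h); gpm <- e(h, -h); gmp <- e(-h, h); gmm <- e(-h, -h)
    }
    gx <- (gp0 - gm0) / (2 * h)
    gy <- (g0p - g0m) / (2 * h)
    gxx <- (gp0 - 2 * g0 + gm0) / h^2
    gyy <- (g0p - 2 * g0 + g0m) / h^2
    gxy <- (gpp - gpm - gmp + gmm) / (4 * h^2)
    # ridge to keep the 2x2 Hessian positive definite
    mineig <- (gxx + gyy) / 2 - sqrt(((gxx - gyy) / 2)^2 + gxy^2)
    ridge <- pmax(0, 1e-4 - mineig)
    axx <- gxx + ridge; ayy <- gyy + ridge
    det <- axx * ayy - gxy^2
    s1 <- -(ayy * gx - gxy * gy) / det
    s2 <- -(axx * gy - gxy * gx) / det
    # cap implausible steps
    too_big <- pmax(abs(s1), abs(s2)) > 2
    scl <- ifelse(too_big, 2 / pmax(abs(s1), abs(s2)), 1)
    s1 <- s1 * scl; s2 <- s2 * scl
    # per-subject backtracking line search; |eta| capped at 10 (e^10-fold
    # deviation from typical) to keep the exponentials in range
    m <- rep(1, n)
    for (ls in 1:7) {
      cand <- cbind(pmin(pmax(eta[, 1] + m * s1, -10), 10),
                    pmin(pmax(eta[, 2] + m * s2, -10), 10))
      gc <- gfun(cand)
      worse <- gc > g0 + 1e-12
      if (!any(worse)) break
      m[worse] <- m[worse] / 2
    }
    accept <- is.finite(gc) & gc <= g0
    progress <- any(accept & gc < g0 - 1e-13)
    eta[accept, ] <- cand[accept, , drop = FALSE]
    g0 <- ifelse(accept, gc, g0)
    # stop on gradient tolerance or when no subject can improve further
    # (a fully rejected step leaves the Laplace term error far below the
    # objective's numerical precision)
    if (max(abs(gx), abs(gy)) < tol || !progress) break
  }
  list(eta = eta, g = g0, gxx = gxx, gyy = gyy, gxy = gxy,
       grad_max = max(abs(gx), abs(gy)))
}

# Parameter packing: (log cl_typ, cl exponents..., log v_typ, v exponents...,
# log omega2_cl, log omega2_v, log sigma2).
pack_names <- function(struct) {
  c("log_cl_typ",
    if (length(struct$cl_cov)) paste0("cl_", names(struct$cl_cov), "_exp"),
    "log_v_typ",
    if (length(struct$v_cov)) paste0("v_", names(struct$v_cov), "_exp"),
    "log_omega2_cl", "log_omega2_v", "log_sigma2")
}

pack_params <- function(p, struct) {
  exp_init <- function(side, nm) {
    if (side == "cl" && nm == "CLCR") return(p$clcr_exp)
    if (side == "cl" && nm == "WT") return(p$wt_exp_cl)
    if (side == "v" && nm == "AGE") return(p$age_exp_v)
    if (side == "v" && nm == "WT") return(p$wt_exp_v)
    0.1
  }
  out <- c(log(p$cl_typ),
           vapply(names(struct$cl_cov), function(nm) exp_init("cl", nm), 0),
           log(p$v_typ),
           vapply(names(struct$v_cov), function(nm) exp_init("v", nm), 0),
           log(p$omega2_cl), log(p$omega2_v), log(p$sigma2_prop))
  names(out) <- pack_names(struct)
  out
}

unpack_params <- function(par, struct) {
  ncl <- length(struct$cl_cov)
  nv <- length(struct$v_cov)
  i <- 1
  cl_typ <- exp(par[i]); i <- i + 1
  cl_exp <- if (ncl) stats::setNames(par[i:(i + ncl - 1)],
                                     names(struct$cl_cov)) else numeric(0)
  i <- i + ncl
  v_typ <- exp(par[i]); i <- i + 1
  v_exp <- if (nv) stats::setNames(par[i:(i + nv - 1)],
                                   names(struct$v_cov)) else numeric(0)
  i <- i + nv
  list(cl_typ = cl_typ, cl_exp = cl_exp, v_typ = v_typ, v_exp = v_exp,
       omega2 = exp(par[c(i, i + 1)]), sigma2 = exp(par[i + 2]))
}

# Objective-function factory with warm-started inner modes.
make_outer_objective <- function(prep, struct, inner_tol = 1e-8) {
  env <- new.env(parent = emptyenv())
  env$eta <- matrix(0, prep$n_subj, 2)
  stack <- make_stack(prep, 9L)
  obj <- function(par) {
    th <- unpack_params(par, struct)
    base_lcl <- log(th$cl_typ) + as.numeric(prep$Xcl %*% th$cl_exp)
    base_lv <- log(th$v_typ) + as.numeric(prep$Xv %*% th$v_exp)
    gfun <- function(eta) g_all(prep, base_lcl, base_lv, th$omega2,
                                th$sigma2, eta)
    gfun_multi <- function(eta, offsets)
      g_stack(stack, base_lcl, base_lv, th$omega2, th$sigma2, eta, offsets)
    sol <- tryCatch(inner_newton(gfun, env$eta, tol = inner_tol,
                                 gfun_multi = gfun_multi),
                    error = function(e) NULL)
    if (is.null(sol)) return(1e10)
    env$eta <- sol$eta
    det_h <- sol$gxx * sol$gyy - sol$gxy^2
    if (any(!is.finite(det_h)) || any(det_h <= 0)) return(1e10)
    ofv <- sum(sol$g) + prep$n_obs * log(2 * pi) -
      2 * prep$n_subj * log(2 * pi) + sum(log(det_h / 4))
    if (!is.finite(ofv)) return(1e10)
    ofv
  }
  list(objective = obj, env = env)
}

# Central-difference Hessian of fn at x (used for asymptotic SEs).
num_hessian <- function(fn, x, h = NULL) {
  p <- length(x)
  # steps sized well above the objective's inner-optimization noise floor;
  # second differences are stable for h in roughly [3e-3, 3e-2] here
  if (is.null(h)) h <- pmax(5e-3, 5e-3 * abs(x))
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}
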