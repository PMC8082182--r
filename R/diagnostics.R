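#' Goodness-of-fit quantities: PRED, IPRED and CWRES
#'
#' Computes population predictions (\code{PRED}, at \eqn{\eta = 0}),
#' individual predictions (\code{IPRED}, at the conditional modes
#' \eqn{\hat\eta}) and conditional weighted residuals (\code{CWRES}) by the
#' standard FOCE linearization about \eqn{\hat\eta}: with
#' \eqn{G_i = \partial f_i/\partial \eta} at the mode,
#' \eqn{Cov_i = G_i \Omega G_i' + diag(\sigma^2 \hat f_i^2)} and
#' \eqn{CWRES_i = Cov_i^{-1/2} (y_i - \hat f_i + G_i \hat\eta_i)}.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param fit a \code{popk_fit} from \code{\link{fit_popk}}, or
#'   \code{\link{population_parameters}} (the conditional modes are then
#'   computed by \code{\link{map_eta}}-style inner optimization).
#' @param include_blq include BLQ rows (LLOQ/2)?
#' @return A data.frame with columns \code{ID}, \code{TIME}, \code{DV},
#'   \code{PRED}, \code{IPRED}, \code{CWRES}; subjects whose conditional
#'   covariance is numerically singular get \code{NA} CWRES and are listed
#'   in \code{attr(, "flagged")}.
#' @export
cwres <- function(ds, fit, include_blq = FALSE) {
  if (inherits(fit, "popk_fit")) {
    p <- fit$params
    if (is.null(p)) stop("fit does not use the canonical covariate model",
                         call. = FALSE)
    struct <- fit$model
  } else {
    p <- fit
    struct <- pk_structure()
  }
  prep <- prepare_nlme(ds, struct, include_blq = include_blq)
  base_lcl <- log(clearance(prep$cov, 0, p))
  base_lv <- log(volume(prep$cov, 0, p))
  omega2 <- c(p$omega2_cl, p$omega2_v)
  gfun <- function(eta) g_all(prep, base_lcl, base_lv, omega2,
                              p$sigma2_prop, eta)
  eta <- if (inherits(fit, "popk_fit") && nrow(fit$eta) == prep$n_subj)
    fit$eta else inner_newton(gfun, matrix(0, prep$n_subj, 2))$eta

  h <- 1e-5
  fhat <- predict_conc(prep, base_lcl + eta[, 1], base_lv + eta[, 2])
  g1 <- (predict_conc(prep, base_lcl + eta[, 1] + h, base_lv + eta[, 2]) -
           predict_conc(prep, base_lcl + eta[, 1] - h,
                        base_lv + eta[, 2])) / (2 * h)
  g2 <- (predict_conc(prep, base_lcl + eta[, 1], base_lv + eta[, 2] + h) -
           predict_conc(prep, base_lcl + eta[, 1],
                        base_lv + eta[, 2] - h)) / (2 * h)
  pred <- predict_conc(prep, base_lcl, base_lv)

  cw <- rep(NA_real_, prep$n_obs)
  flagged <- character(0)
  Om <- diag(omega2)
  for (s in seq_len(prep$n_subj)) {
    idx <- which(prep$obs_subj == s)
    if (!length(idx)) next
    G <- cbind(g1[idx], g2[idx])
    Cov <- G %*% Om %*% t(G) + diag(p$sigma2_prop * fhat[idx]^2,
                                    length(idx))
    res <- prep$obs_y[idx] - fhat[idx] + as.numeric(G %*% eta[s, ])
    ch <- tryCatch(chol(Cov), error = function(e) NULL)
    if (is.null(ch)) {
      flagged <- c(flagged, as.character(prep$ids[s]))
      next
    }
    cw[idx] <- backsolve(ch, res, transpose = TRUE)
  }
  out <- data.frame(ID = prep$ids[prep$obs_subj],
                    TIME = ds$TIME[ds$EVID == 0 & ds$MDV == 0 &
                                     (include_blq | ds$BLQ != 1)],
                    DV = prep$obs_y, PRED = pred, IPRED = fhat, CWRES = cw,
                    stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  out
}

#' Visual predictive check
#'
#' Simulates \code{n_sim} replicate datasets under the design of \code{ds}
#' (same subjects, covariates, dosing histories and sampling times; fresh
#' \eqn{\eta} and residual draws), bins observations on time since first
#' dose, and compares the observed 2.5th/50th/97.5th percentiles per bin
#' with their simulation-based 95\% confidence bands.
#'
#' @param ds a \code{\link{tdm_dataset}}.
#' @param p \code{\link{population_parameters}}.
#' @param n_sim number of simulated replicates (>= 100 recommended).
#' @param bins number of quantile-based time bins (bins with fewer than 5
#'   observations are merged with a neighbor, with a warning).
#' @param seed integer RNG seed.
#' @param include_blq include BLQ rows of the observed data?
#' @return A list of class \code{vpc_result} with \code{bins}: a data.frame
#'   of bin bounds, n, observed percentiles (\code{obs_p2.5, obs_p50,
#'   obs_p97.5}) and simulated 95\% bands (\code{lo_*, hi_*}); and
#'   \code{n_sim}.
#' @export
vpc <- function(ds, p, n_sim = 200L, bins = 4L, seed = 1L,
                include_blq = TRUE) {
  stopifnot(n_sim >= 2)
  prep <- prepare_nlme(ds, include_blq = include_blq)
  base_lcl <- log(clearance(prep$cov, 0, p))
  base_lv <- log(volume(prep$cov, 0, p))
  time <- ds$TIME[ds$EVID == 0 & ds$MDV == 0 & (include_blq | ds$BLQ != 1)]

  breaks <- unique(stats::quantile(time, probs = seq(0, 1,
                                                     length.out = bins + 1)))
  if (length(breaks) < 2) breaks <- range(time) + c(-1e-9, 1e-9)
  bin <- cut(time, breaks, include.lowest = TRUE, labels = FALSE)
  # merge small bins with the left neighbor
  repeat {
    counts <- table(factor(bin, levels = seq_len(max(bin))))
    small <- which(counts < 5 & counts > 0)
    if (!length(small) || length(unique(bin)) == 1) break
    b <- small[1]
    warning("merging VPC bin with fewer than 5 observations", call. = FALSE)
    bin[bin == b] <- if (b > 1) b - 1 else b + 1
    bin <- match(bin, sort(unique(bin)))
  }
  probs <- c(0.025, 0.5, 0.975)
  obs_pct <- t(vapply(sort(unique(bin)), function(b)
    stats::quantile(prep$obs_y[bin == b], probs), numeric(3)))

  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(r) {
      eta <- cbind(stats::rnorm(prep$n_subj, 0, sqrt(p$omega2_cl)),
                   stats::rnorm(prep$n_subj, 0, sqrt(p$omega2_v)))
      f <- predict_conc(prep, base_lcl + eta[, 1], base_lv + eta[, 2])
      y <- f * (1 + stats::rnorm(prep$n_obs, 0, sqrt(p$sigma2_prop)))
      # columns per bin, percentiles within column: dim (3, n_bins)
      as.numeric(vapply(sort(unique(bin)), function(b)
        stats::quantile(y[bin == b], probs), numeric(3)))
    }, numeric(3 * length(unique(bin))))
  })
  n_bins <- length(unique(bin))
  sim_arr <- array(sims, dim = c(3, n_bins, n_sim))
  lo <- apply(sim_arr, c(2, 1), stats::quantile, probs = 0.025)
  hi <- apply(sim_arr, c(2, 1), stats::quantile, probs = 0.975)
  bins_df <- data.frame(
    bin = seq_len(n_bins),
    t_lo = vapply(seq_len(n_bins), function(b) min(time[bin == b]), 0),
    t_hi = vapply(seq_len(n_bins), function(b) max(time[bin == b]), 0),
    n = as.integer(table(bin)),
    obs_p2.5 = obs_pct[, 1], obs_p50 = obs_pct[, 2],
    obs_p97.5 = obs_pct[, 3],
    lo_p2.5 = lo[, 1], hi_p2.5 = hi[, 1],
    lo_p50 = lo[, 2], hi_p50 = hi[, 2],
    lo_p97.5 = lo[, 3], hi_p97.5 = hi[, 3])
  structure(list(bins = bins_df, n_sim = n_sim), class = "vpc_result")
}

#' Random-effect shrinkage
#'
#' \eqn{100 (1 - SD(\hat\eta)/\sqrt{\omega^2})} per random effect: 100\%
#' when all conditional modes collapse to zero (no individual information),
#' 0\% when their spread matches the population variance.
#'
#' @param eta_hats matrix (subjects x effects) or vector of conditional
#'   modes.
#' @param omega2 corresponding IIV variance(s), > 0.
#' @return Shrinkage percentage(s).
#' @export
shrinkage <- function(eta_hats, omega2) {
  eta_hats <- as.matrix(eta_hats)
  if (nrow(eta_hats) < 2)
    stop("shrinkage is undefined for fewer than 2 subjects", call. = FALSE)
  if (any(omega2 <= 0)) stop("'omega2' must be positive", call. = FALSE)
  100 * (1 - apply(eta_hats, 2, stats::sd) / sqrt(omega2))
}

#' External-validation prediction errors
#'
#' Mean prediction error (\%), mean absolute prediction error (\%) and root
#' mean squared error of paired predictions against observations.
#'
#' @param observed observed values, > 0.
#' @param predicted predicted values, same length.
#' @return A named list: \code{mpe_pct}, \code{mape_pct}, \code{rmse}.
#' @export
prediction_errors <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (any(observed <= 0))
    stop("'observed' must be strictly positive", call. = FALSE)
  rel <- (predicted - observed) / observed
  list(mpe_pct = 100 * mean(rel), mape_pct = 100 * mean(abs(rel)),
       rmse = sqrt(mean((predicted - observed)^2)))
}
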