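#' Multivariate logistic regression with per-term Wald tests
#'
#' Fits a maximum-likelihood logistic regression (via iteratively
#' reweighted least squares, \code{stats::glm}) of a binary outcome on the
#' given terms and reports a Wald chi-squared statistic per term:
#' \eqn{(\hat\beta/SE)^2} (1 df) for scalar terms and
#' \eqn{\hat\beta' V^{-1} \hat\beta} (multi-df) for categorical terms.
#' Categorical terms use reference-cell coding with the most frequent level
#' as reference. Complete separation is flagged and the affected term
#' reported as inestimable (\code{NA}).
#'
#' @param data a data.frame of outcome records (e.g. from
#'   \code{\link{simulate_outcomes}}).
#' @param response name of the binary response column.
#' @param terms character vector of predictor column names.
#' @return A data.frame with columns \code{term}, \code{df},
#'   \code{wald_chisq}, \code{p_value}, \code{estimable}; the fitted
#'   \code{glm} is attached as \code{attr(, "fit")}.
#' @export
logistic_wald <- function(data, response, terms) {
  y <- data[[response]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("response must have at least one event and one non-event",
         call. = FALSE)
  df <- data[, c(response, terms), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (tm in terms) {
    if (is.character(df[[tm]]) || is.factor(df[[tm]])) {
      tabl <- sort(table(df[[tm]]), decreasing = TRUE)
      df[[tm]] <- factor(df[[tm]], levels = names(tabl))
    }
  }
  form <- stats::reformulate(terms, response)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  asgn <- attr(stats::model.matrix(fit), "assign")
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  term_labels <- attr(stats::terms(fit), "term.labels")
  rows <- lapply(seq_along(term_labels), function(k) {
    idx <- which(asgn == k)
    b <- beta[idx]
    bad <- sep_warned && any(abs(b) > 10)
    bad <- bad || any(is.na(b)) || any(sqrt(diag(V)[idx]) > 100)
    if (bad) {
      return(data.frame(term = term_labels[k], df = length(idx),
                        wald_chisq = NA_real_, p_value = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
    data.frame(term = term_labels[k], df = length(idx), wald_chisq = W,
               p_value = stats::pchisq(W, length(idx), lower.tail = FALSE),
               estimable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

#' Exact test for an r x c contingency table
#'
#' Two-sided Fisher exact test by full enumeration of all tables with the
#' observed margins: the p-value is the total hypergeometric probability of
#' tables whose probability does not exceed the observed table's
#' (probability-ordering rule, stated explicitly because r x c two-sided
#' conventions vary).
#'
#' @param tab an r x c matrix of non-negative integer counts.
#' @param enumeration_bound refuse tables with a grand total above this
#'   (default 200); larger tables would need a Monte Carlo p-value, which is
#'   out of scope here.
#' @return The two-sided exact p-value in (0, 1].
#' @export
fisher_exact_rxc <- function(tab, enumeration_bound = 200) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must contain non-negative integer counts", call. = FALSE)
  N <- sum(tab)
  if (N <= 0) stop("'tab' must have a positive total", call. = FALSE)
  if (N > enumeration_bound)
    stop("table total ", N, " exceeds the enumeration bound (",
         enumeration_bound, "); use a Monte Carlo test instead",
         call. = FALSE)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  r <- rowSums(tab)
  cs <- colSums(tab)
  nr <- nrow(tab)
  nc <- ncol(tab)
  lfac <- lgamma(seq.int(0, N) + 1)
  const <- sum(lfac[r + 1]) + sum(lfac[cs + 1]) - lfac[N + 1]
  logp_obs <- const - sum(lfac[tab + 1])
  total <- 0
  enumerate <- function(row, colrem, acc) {
    if (row > nr) {
      lp <- const - acc
      if (lp <= logp_obs + 1e-7) total <<- total + exp(lp)
      return(invisible())
    }
    if (row == nr) {
      # last row is forced by the remaining column margins
      return(enumerate(nr + 1L, colrem * 0L, acc + sum(lfac[colrem + 1])))
    }
    fill <- function(j, rem, colrem, acc) {
      if (j == nc) {
        if (rem > colrem[nc]) return(invisible())
        enumerate(row + 1L, replace(colrem, nc, colrem[nc] - rem),
                  acc + lfac[rem + 1])
        return(invisible())
      }
      for (a in 0:min(rem, colrem[j]))
        fill(j + 1L, rem - a, replace(colrem, j, colrem[j] - a),
             acc + lfac[a + 1])
    }
    fill(1L, r[row], colrem, acc)
  }
  enumerate(1L, cs, 0)
  min(total, 1)
}

#' Grouped PK/PD summaries by infection site and response
#'
#' For the overall cohort and each infection site, reports the number and
#' percentage of responders/non-responders and the median and interquartile
#' range of each PK/PD index by response status. IQRs are suppressed
#' (\code{NA}) for groups with fewer than 5 records.
#'
#' @param records outcome records (one row per subject) containing the
#'   response, site and index columns.
#' @param response_col binary response column name (default
#'   \code{"clinical_improved"}).
#' @param site_col infection-site column name.
#' @param value_cols index columns to summarize.
#' @return A data.frame with columns \code{site}, \code{response},
#'   \code{n}, \code{pct}, \code{variable}, \code{median}, \code{q1},
#'   \code{q3}.
#' @export
group_summaries <- function(records, response_col = "clinical_improved",
                            site_col = "infection_site",
                            value_cols = c("auc24", "auc24_over_mic")) {
  if (nrow(records) == 0) stop("'records' is empty", call. = FALSE)
  sites <- c("Overall", sort(unique(records[[site_col]])))
  rows <- list()
  for (s in sites) {
    sub <- if (s == "Overall") records else
      records[records[[site_col]] == s, , drop = FALSE]
    n_tot <- nrow(sub)
    for (resp in c(1L, 0L)) {
      grp <- sub[sub[[response_col]] == resp, , drop = FALSE]
      n <- nrow(grp)
      for (v in value_cols) {
        qs <- if (n > 0) stats::quantile(grp[[v]], c(0.25, 0.5, 0.75),
                                         na.rm = TRUE)
        else rep(NA_real_, 3)
        rows[[length(rows) + 1L]] <- data.frame(
          site = s, response = if (resp == 1L) "improved" else "not improved",
          n = n, pct = round(100 * n / n_tot, 1), variable = v,
          median = qs[2],
          q1 = if (n >= 5) qs[1] else NA_real_,
          q3 = if (n >= 5) qs[3] else NA_real_,
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
  }
  do.call(rbind, rows)
}

#' MIC distribution summary
#'
#' MIC50 (MIC90) is the lowest concentration on the doubling-dilution grid
#' at which at least 50\% (90\%) of the isolates are inhibited, i.e. the
#' smallest grid value whose cumulative isolate fraction reaches the
#' percentile.
#'
#' @param mics vector of isolate MICs (mg/L) on a doubling-dilution grid.
#' @return A list of class \code{mic_summary}: \code{mic50}, \code{mic90},
#'   \code{grid}, \code{n}.
#' @export
mic_summary <- function(mics) {
  if (length(mics) == 0) stop("'mics' is empty", call. = FALSE)
  if (any(mics <= 0)) stop("MICs must be positive", call. = FALSE)
  k <- log2(mics / 0.125)
  if (any(abs(k - round(k)) > 1e-8))
    stop("MICs must lie on the doubling-dilution grid (0.125 x 2^k)",
         call. = FALSE)
  grid <- sort(unique(mics))
  cum <- vapply(grid, function(g) mean(mics <= g), 0)
  out <- list(mic50 = grid[which(cum >= 0.5)[1]],
              mic90 = grid[which(cum >= 0.9)[1]],
              grid = grid, n = length(mics))
  structure(out, class = "mic_summary")
}
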