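values_of <- function(series) {
  if (inherits(series, "annual_series")) series$values else as.numeric(series)
}

#' Remove a linear secular trend, preserving the mean
#'
#' Ordinary least squares of value on calendar year; the returned series is
#' the residuals plus the original long-term mean, so the baseline phenotype
#' is identical across the raw and residual model variants.
#'
#' @param series An [annual_series()].
#' @return A list with `series` (detrended [annual_series()]) and `slope`
#'   (units per year).
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "annual_series"))
  n <- length(series$values)
  if (n < 3L) stop("insufficient data: need at least 3 years", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, series$years), series$values)
  out <- annual_series(series$site_id, series$variable, series$years,
                       as.numeric(fit$residuals) + mean(series$values))
  list(series = out, slope = unname(fit$coefficients[2L]))
}

#' Autocorrelation by overlapping-window Pearson correlation
#'
#' The lag-k autocorrelation is the plain Pearson correlation between the
#' series and itself shifted by k years ("cropped" estimator): each window
#' is standardised by its own mean and variance.  This matches the verbal
#' definition "correlation between year X and year X + k" and differs from
#' the standardised-by-full-variance estimator by O(1/n).
#'
#' @param series An [annual_series()] or numeric vector.
#' @param max_lag Largest lag to compute.
#' @return Numeric vector of correlations at lags `1..max_lag`.
#' @export
acf_annual <- function(series, max_lag = 12L) {
  x <- values_of(series)
  n <- length(x)
  if (n <= max_lag + 2L) {
    stop("insufficient data: need length > max_lag + 2", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate input: zero-variance series", call. = FALSE)
  }
  vapply(seq_len(max_lag), function(k) {
    stats::cor(x[seq_len(n - k)], x[(1L + k):n])
  }, numeric(1))
}

#' Partial autocorrelation via Levinson-Durbin
#'
#' The lag-k partial autocorrelation is the correlation between years t and
#' t + k after regressing out the intervening lags; computed as the
#' reflection coefficients of the Levinson-Durbin recursion applied to the
#' sample autocorrelations of [acf_annual()].  Algebraically identical to
#' the partial correlation obtained by inverting the Toeplitz correlation
#' matrix (the regression route used as an oracle in the tests).
#'
#' @inheritParams acf_annual
#' @return Numeric vector of partial correlations at lags `1..max_lag`.
#' @export
pacf_annual <- function(series, max_lag = 12L) {
  rho <- acf_annual(series, max_lag)
  pacf_from_acf(rho)
}

# Levinson-Durbin: reflection coefficients from an autocorrelation sequence
pacf_from_acf <- function(rho) {
  p <- length(rho)
  phi <- numeric(p)
  a <- numeric(0)
  for (k in seq_len(p)) {
    if (k == 1L) {
      phi[1L] <- rho[1L]
      a <- rho[1L]
    } else {
      num <- rho[k] - sum(a * rho[(k - 1L):1L])
      den <- 1 - sum(a * rho[seq_len(k - 1L)])
      phi[k] <- num / den
      a <- c(a - phi[k] * rev(a), phi[k])
    }
  }
  phi
}

#' Lagged cross-correlation between two annual series
#'
#' Pearson correlation of `a` at year t - lag with `b` at year t over the
#' shared years.
#'
#' @param a,b [annual_series()] objects with identical year labels.
#' @param lag Non-negative integer lag applied to `a`.
#' @return A single correlation.
#' @export
cross_corr <- function(a, b, lag = 0L) {
  stopifnot(inherits(a, "annual_series"), inherits(b, "annual_series"))
  if (!identical(a$years, b$years)) {
    stop("series must share identical year labels", call. = FALSE)
  }
  x <- a$values; y <- b$values; n <- length(x)
  if (n - lag < 3L) stop("insufficient data for lag ", lag, call. = FALSE)
  xs <- x[seq_len(n - lag)]
  ys <- y[(1L + lag):n]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("degenerate input: zero variance in a correlation window",
         call. = FALSE)
  }
  stats::cor(xs, ys)
}

safe_stat <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

#' Per-site climate summary statistics
#'
#' Computes, for an annual series (or each member of a seasonal pair), the
#' long-term mean, interannual standard deviation (IASD), linear trend
#' slope, ACF and PACF at lags 1..12, and the lag-1 ACF of the linearly
#' detrended series.  For a seasonal pair the five season-to-season
#' correlations are added: `ee_acf` = cor(E[t-1], E[t]), `el_acf` =
#' cor(E[t-1], L[t]), `le_acf` = cor(L[t-1], E[t]), `ll_acf` =
#' cor(L[t-1], L[t]) and `within_acf` = cor(E[t], L[t]).  Degenerate
#' statistics are recorded as `NA` rather than raised, so batch runs stay
#' alive; the underlying operations still error when called directly.
#'
#' @param x An [annual_series()] or [seasonal_series()].
#' @param max_lag Largest ACF/PACF lag retained (default 12).
#' @return A one-row (annual) or two-row (seasonal) `data.frame` with
#'   columns `site_id`, `variable`, `mean`, `iasd`, `trend_slope`,
#'   `acf1..acf<max_lag>`, `pacf1..pacf<max_lag>`, `res_acf1`, `ee_acf`,
#'   `el_acf`, `le_acf`, `ll_acf`, `within_acf`.
#' @export
site_summary <- function(x, max_lag = 12L) {
  if (inherits(x, "seasonal_series")) {
    rows <- rbind(site_summary(x$early, max_lag), site_summary(x$late, max_lag))
    rows$ee_acf <- safe_stat(cross_corr(x$early, x$early, 1L))
    rows$el_acf <- safe_stat(cross_corr(x$early, x$late, 1L))
    rows$le_acf <- safe_stat(cross_corr(x$late, x$early, 1L))
    rows$ll_acf <- safe_stat(cross_corr(x$late, x$late, 1L))
    rows$within_acf <- safe_stat(cross_corr(x$early, x$late, 0L))
    return(rows)
  }
  stopifnot(inherits(x, "annual_series"))
  n <- length(x$values)
  # shrink the lag range on short series; pad the summary with NA
  feasible <- max(0L, min(max_lag, n - 3L))
  ac <- rep(NA_real_, max_lag)
  pc <- rep(NA_real_, max_lag)
  if (feasible > 0L) {
    ac[seq_len(feasible)] <- safe_stat(acf_annual(x, feasible))
    pc[seq_len(feasible)] <- safe_stat(pacf_annual(x, feasible))
  }
  dt <- safe_stat(detrend_linear(x)$slope)
  res1 <- safe_stat(acf_annual(detrend_linear(x)$series, 1L))
  out <- data.frame(site_id = x$site_id, variable = x$variable,
                    mean = mean(x$values), iasd = stats::sd(x$values),
                    trend_slope = dt, stringsAsFactors = FALSE)
  for (k in seq_len(max_lag)) out[[paste0("acf", k)]] <- ac[k]
  for (k in seq_len(max_lag)) out[[paste0("pacf", k)]] <- pc[k]
  out$res_acf1 <- res1
  out$ee_acf <- NA_real_; out$el_acf <- NA_real_; out$le_acf <- NA_real_
  out$ll_acf <- NA_real_; out$within_acf <- NA_real_
  out
}
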