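# Independent oracles, deliberately written on different computational
# routes than the package internals.

# geometric-mean fitness by naive per-year direct product (precipitation)
oracle_precip_gm <- function(series, strategy, eps = 1e-6) {
  n <- length(series$values)
  ws <- numeric(0)
  for (t in 4:n) {
    ph <- predict_precip_phenotype(series, strategy, t)
    ws <- c(ws, max(eps, 1 - abs(ph - series$values[t]) / series$baseline))
  }
  prod(ws)^(1 / length(ws))
}

# geometric-mean fitness by naive direct product (temperature)
oracle_temp_gm <- function(seasonal, strategy, eps = 1e-6,
                           scale = c("mean", "iasd")) {
  scale <- match.arg(scale)
  n <- length(seasonal$years)
  sE <- if (scale == "mean") seasonal$early$baseline else sd(seasonal$early$values)
  sL <- if (scale == "mean") seasonal$late$baseline else sd(seasonal$late$values)
  ws <- numeric(0)
  for (t in 2:n) {
    ph <- predict_season_phenotypes(seasonal, strategy, t)
    ws <- c(ws,
            max(eps, 1 - abs(ph[["early"]] - seasonal$early$values[t]) / sE),
            max(eps, 1 - abs(ph[["late"]] - seasonal$late$values[t]) / sL))
  }
  prod(ws)^(1 / length(ws))
}

# PACF by the regression route: partial correlation between x_t and x_{t+k}
# controlling the intervening lags, from the inverse of the Toeplitz
# correlation matrix built on the same sample autocorrelations
oracle_pacf <- function(series, max_lag) {
  r <- acf_annual(series, max_lag)
  vapply(seq_len(max_lag), function(k) {
    if (k == 1L) return(r[1L])
    R <- stats::toeplitz(c(1, r[seq_len(k)]))
    P <- solve(R)
    -P[1L, k + 1L] / sqrt(P[1L, 1L] * P[k + 1L, k + 1L])
  }, numeric(1))
}

# brute-force hydrologic-year totals straight off the monthly table
oracle_hydro_totals <- function(table, site_id) {
  rows <- table[table$site_id == site_id, ]
  yrs <- sort(unique(ifelse(rows$month >= 10, rows$year + 1L, rows$year)))
  out <- list()
  for (y in yrs) {
    sel <- (rows$year == y - 1L & rows$month >= 10L) |
      (rows$year == y & rows$month <= 9L)
    v <- rows$ppt_mm[sel]
    if (length(v) == 12L && !anyNA(v)) out[[as.character(y)]] <- sum(v)
  }
  out
}

random_series <- function(n = 60, seed = 1, mean = 100, sd = 15) {
  set.seed(seed)
  annual_series(paste0("R", seed), "precip", seq_len(n) + 1900L,
                rnorm(n, mean, sd))
}

random_seasonal <- function(n = 40, seed = 1) {
  set.seed(seed)
  yrs <- seq_len(n) + 1900L
  seasonal_series(
    annual_series(paste0("R", seed), "tmax_early", yrs, rnorm(n, 10.4, 1.2)),
    annual_series(paste0("R", seed), "tmax_late", yrs, rnorm(n, 21.2, 0.9)))
}
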