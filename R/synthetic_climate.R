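#' AR coefficients from partial autocorrelations
#'
#' Levinson-Durbin step-up recursion: the partial autocorrelations
#' `phi_kk` at lags 1..p are the reflection coefficients of a stationary
#' AR(p) process, and this routine converts them to the autoregressive
#' coefficients `a_1..a_p`.  Any sequence with all `|phi_kk| < 1` yields a
#' stationary model, which is why the simulator is parameterised by PACF
#' rather than by ACF or by raw AR coefficients.
#'
#' @param pacf_targets Numeric vector of partial autocorrelations, each in
#'   (-1, 1).
#' @return Numeric vector of AR coefficients of the same length.
#' @export
#' @examples
#' ar_coeffs_from_pacf(0.4)         # AR(1): coefficient equals lag-1 PACF
#' ar_coeffs_from_pacf(c(0.2, 0.3)) # c(0.14, 0.3)
ar_coeffs_from_pacf <- function(pacf_targets) {
  phi <- as.numeric(pacf_targets)
  if (length(phi) == 0L) return(numeric(0))
  if (any(!is.finite(phi)) || any(abs(phi) >= 1)) {
    stop("domain error: all partial autocorrelations must satisfy |phi| < 1",
         call. = FALSE)
  }
  a <- numeric(0)
  for (k in seq_along(phi)) {
    if (k == 1L) {
      a <- phi[1L]
    } else {
      a <- c(a - phi[k] * rev(a), phi[k])
    }
  }
  a
}

#' Specification of a synthetic annual climate series
#'
#' @param n_years Number of years to generate.
#' @param mean Long-term mean in series units (mm or degrees C).
#' @param sd Marginal interannual standard deviation (must be > 0).
#' @param pacf_targets Partial autocorrelations phi_kk for lags 1..p; the
#'   generated AR(p) has exactly these theoretical PACF values.
#' @param trend Linear trend in units per year, added centred on the series
#'   midpoint so the long-term mean is preserved.
#' @param seed Integer seed; the realisation is a deterministic function of
#'   the spec.
#' @param start_year First year label.
#' @return A list of class `annual_sim_spec`.
#' @export
annual_sim_spec <- function(n_years, mean, sd, pacf_targets = numeric(0),
                            trend = 0, seed = 1L, start_year = 1895L) {
  p <- length(pacf_targets)
  if (n_years < p + 5L) {
    stop("n_years must be at least length(pacf_targets) + 5", call. = FALSE)
  }
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (p > 0 && any(abs(pacf_targets) >= 1)) {
    stop("domain error: all |phi_kk| < 1 required", call. = FALSE)
  }
  structure(list(n_years = as.integer(n_years), mean = mean, sd = sd,
                 pacf_targets = as.numeric(pacf_targets), trend = trend,
                 seed = as.integer(seed), start_year = as.integer(start_year)),
            class = "annual_sim_spec")
}

# run `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an annual climate series
#'
#' Generates a stationary Gaussian AR(p) deviation process whose theoretical
#' PACF at lags 1..p equals `spec$pacf_targets` and whose marginal standard
#' deviation equals `spec$sd` (the innovation variance is
#' `sd^2 * prod(1 - phi_kk^2)`), discards a 200-step burn-in, then adds the
#' mean and a mean-preserving centred linear trend.
#'
#' @param spec An [annual_sim_spec()].
#' @param site_id Site label for the output series.
#' @param variable Output variable tag.
#' @param clip_zero If `TRUE`, clip values at 0 (precipitation only;
#'   default off so moments are exact).
#' @return An [annual_series()].
#' @export
simulate_annual_series <- function(spec, site_id = "synthetic",
                                   variable = "precip", clip_zero = FALSE) {
  stopifnot(inherits(spec, "annual_sim_spec"))
  a <- ar_coeffs_from_pacf(spec$pacf_targets)
  p <- length(a)
  burn <- 200L
  n_tot <- spec$n_years + burn
  innov_sd <- spec$sd * sqrt(prod(1 - spec$pacf_targets^2))
  dev <- with_seed(spec$seed, {
    e <- stats::rnorm(n_tot, 0, innov_sd)
    if (p == 0L) e else {
      x <- numeric(n_tot)
      for (t in seq_len(n_tot)) {
        hist_idx <- t - seq_len(min(p, t - 1L))
        x[t] <- sum(a[seq_along(hist_idx)] * x[hist_idx]) + e[t]
      }
      x
    }
  })
  dev <- dev[(burn + 1L):n_tot]
  idx <- seq_len(spec$n_years)
  vals <- spec$mean + dev + spec$trend * (idx - mean(idx))
  if (clip_zero) vals <- pmax(vals, 0)
  years <- spec$start_year + idx - 1L
  annual_series(site_id, variable, years, vals)
}

#' Specification of a paired early/late seasonal simulation
#'
#' Deviations from the two seasonal means follow a first-order vector
#' autoregression
#' \deqn{z_t = A z_{t-1} + e_t,\quad e_t \sim N(0, \Sigma),}
#' with `A = var1_matrix` (rows/cols ordered early, late) and innovation
#' correlation `within_year_corr`.  Each component is rescaled so the
#' marginal SDs equal `sds`; rescaling preserves every correlation.
#'
#' @param n_years Number of years.
#' @param means Length-2 vector (early, late) of seasonal means in degrees C.
#' @param sds Length-2 vector of marginal interannual SDs.
#' @param var1_matrix 2x2 lag-1 coefficient matrix on (E, L) deviations;
#'   entry `[i, j]` is the effect of season j at year t-1 on season i at
#'   year t.  Spectral radius must be < 1.
#' @param within_year_corr Innovation correlation between E and L
#'   (|r| < 1).
#' @param trends Length-2 vector of centred linear trends (deg C / year).
#' @param seed Integer seed.
#' @param start_year First year label.
#' @return A list of class `seasonal_sim_spec`.
#' @export
seasonal_sim_spec <- function(n_years, means = c(10.4, 21.2),
                              sds = c(1.2, 0.9),
                              var1_matrix = matrix(0, 2, 2),
                              within_year_corr = 0, trends = c(0, 0),
                              seed = 1L, start_year = 1895L) {
  var1_matrix <- matrix(as.numeric(var1_matrix), 2, 2)
  if (max(Mod(eigen(var1_matrix, only.values = TRUE)$values)) >= 1) {
    stop("domain error: var1_matrix must have spectral radius < 1",
         call. = FALSE)
  }
  if (abs(within_year_corr) >= 1) {
    stop("domain error: |within_year_corr| < 1 required", call. = FALSE)
  }
  stopifnot(length(means) == 2L, length(sds) == 2L, all(sds > 0),
            length(trends) == 2L, n_years >= 6L)
  structure(list(n_years = as.integer(n_years), means = as.numeric(means),
                 sds = as.numeric(sds), var1_matrix = var1_matrix,
                 within_year_corr = within_year_corr,
                 trends = as.numeric(trends), seed = as.integer(seed),
                 start_year = as.integer(start_year)),
            class = "seasonal_sim_spec")
}

# stationary covariance of z_t = A z_{t-1} + e_t: vec(G) = (I - A x A)^-1 vec(S)
var1_stationary_cov <- function(A, S) {
  matrix(solve(diag(4) - kronecker(A, A), as.vector(S)), 2, 2)
}

#' Simulate a paired early/late seasonal temperature series
#'
#' @param spec A [seasonal_sim_spec()].
#' @param site_id Site label.
#' @return A [seasonal_series()].
#' @export
simulate_seasonal_pair <- function(spec, site_id = "synthetic") {
  stopifnot(inherits(spec, "seasonal_sim_spec"))
  A <- spec$var1_matrix
  S <- matrix(c(1, spec$within_year_corr, spec$within_year_corr, 1), 2, 2)
  burn <- 200L
  n_tot <- spec$n_years + burn
  L <- chol(S)   # upper triangular, t(L) %*% L = S
  z <- with_seed(spec$seed, {
    e <- matrix(stats::rnorm(2L * n_tot), n_tot, 2L) %*% L
    z <- matrix(0, n_tot, 2L)
    for (t in 2:n_tot) z[t, ] <- as.vector(A %*% z[t - 1L, ]) + e[t, ]
    z
  })
  z <- z[(burn + 1L):n_tot, , drop = FALSE]
  G <- var1_stationary_cov(A, S)
  idx <- seq_len(spec$n_years)
  ctr <- idx - mean(idx)
  years <- spec$start_year + idx - 1L
  mk <- function(j, variable) {
    vals <- spec$means[j] + spec$sds[j] * z[, j] / sqrt(G[j, j]) +
      spec$trends[j] * ctr
    annual_series(site_id, variable, years, vals)
  }
  seasonal_series(mk(1L, "tmax_early"), mk(2L, "tmax_late"))
}

#' Disaggregate an annual series into a monthly climate table
#'
#' Fixture generator: produces monthly records whose window aggregate
#' (hydrologic-year sum for precipitation, 3-month seasonal mean for
#' temperature) reproduces the annual values exactly.  Monthly split within
#' a window is random but seeded.
#'
#' @param annual An [annual_series()].
#' @param seed Integer seed for the within-year split.
#' @param lat,lon Coordinates to stamp on the records.
#' @return A `monthly_climate` table.
#' @export
disaggregate_to_monthly <- function(annual, seed = 1L, lat = 40, lon = -100) {
  stopifnot(inherits(annual, "annual_series"))
  n <- length(annual$values)
  if (annual$variable == "precip") {
    # hydrologic year Y spans Oct(Y-1) .. Sep(Y)
    w <- with_seed(seed, matrix(stats::runif(12L * n, 0.2, 1), n, 12L))
    w <- w / rowSums(w)
    rec <- lapply(seq_len(n), function(i) {
      hy <- annual$years[i]
      months <- c(10:12, 1:9)
      cal_year <- c(rep(hy - 1L, 3L), rep(hy, 9L))
      ppt <- w[i, ] * annual$values[i]
      # make the 12 shares sum exactly (compensate float rounding)
      ppt[12L] <- annual$values[i] - sum(ppt[-12L])
      data.frame(site_id = annual$site_id, lat = lat, lon = lon,
                 year = cal_year, month = months, ppt_mm = ppt,
                 tmax_c = NA_real_, stringsAsFactors = FALSE)
    })
  } else {
    months <- if (annual$variable == "tmax_early") 3:5 else 7:9
    d <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, 2), n, 3L))
    d <- d - rowMeans(d)   # zero-mean offsets keep the seasonal mean exact
    rec <- lapply(seq_len(n), function(i) {
      data.frame(site_id = annual$site_id, lat = lat, lon = lon,
                 year = annual$years[i], month = months,
                 ppt_mm = NA_real_, tmax_c = annual$values[i] + d[i, ],
                 stringsAsFactors = FALSE)
    })
  }
  tab <- do.call(rbind, rec)
  monthly_climate(tab$site_id, tab$lat, tab$lon, tab$year, tab$month,
                  tab$ppt_mm, tab$tmax_c)
}
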