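#' A temperature plasticity genotype
#'
#' Five linear slopes: four transgenerational terms mapping the parental
#' early/late season temperature deviation onto the offspring early/late
#' season phenotype (`m_ee`, `m_el`, `m_le`, `m_ll`; first index = parental
#' cue season, second = offspring response season) and one
#' within-generation term `w` by which the current early-season deviation
#' shifts the late-season phenotype.  The early phenotype cannot respond to
#' its own season's cue.
#'
#' @param m_ee,m_el,m_le,m_ll,w Slopes.
#' @return A list of class `temp_strategy`.
#' @export
temp_strategy <- function(m_ee = 0, m_el = 0, m_le = 0, m_ll = 0, w = 0) {
  structure(list(m_ee = m_ee, m_el = m_el, m_le = m_le, m_ll = m_ll, w = w),
            class = "temp_strategy")
}

#' Default value set for temperature strategy parameters
#'
#' `{-0.2, 0, 0.1, 0.3, 0.5}`: five values whose full factorial over the
#' five slopes gives 5^5 = 3,125 genotypes, spanning weakly negative to
#' moderately positive plasticity.
#' @return Numeric vector of length 5.
#' @export
default_temp_values <- function() c(-0.2, 0, 0.1, 0.3, 0.5)

#' Full-factorial grid of temperature strategies
#'
#' @param values Value set for each of the five parameters.
#' @return A `data.frame` with columns `m_ee`, `m_el`, `m_le`, `m_ll`, `w`;
#'   one row per strategy (`length(values)^5` rows).
#' @export
temp_strategy_grid <- function(values = default_temp_values()) {
  if (length(values) == 0L) stop("domain error: empty value set",
                                 call. = FALSE)
  values <- sort(unique(as.numeric(values)))
  expand.grid(m_ee = values, m_el = values, m_le = values, m_ll = values,
              w = values, KEEP.OUT.ATTRS = FALSE)
}

#' Configuration of the temperature model
#'
#' @param fitness_floor Floor epsilon on per-season fitness (default 1e-6).
#' @param values Strategy parameter value set (see [temp_strategy_grid()]).
#' @param scale `"mean"` (divide the mismatch by the season's long-term
#'   mean, mirroring the precipitation cost) or `"iasd"` (divide by the
#'   season's interannual SD; Celsius has an arbitrary zero, so a
#'   scale-free option is provided).
#' @param variant `"raw"` or `"residual"` (each season detrended
#'   independently).
#' @return A list of class `temp_config`.
#' @export
temp_config <- function(fitness_floor = 1e-6,
                        values = default_temp_values(),
                        scale = c("mean", "iasd"),
                        variant = c("raw", "residual")) {
  scale <- match.arg(scale)
  variant <- match.arg(variant)
  if (!(fitness_floor > 0 && fitness_floor < 0.1)) {
    stop("fitness_floor must lie in (0, 0.1)", call. = FALSE)
  }
  structure(list(fitness_floor = fitness_floor,
                 values = sort(unique(as.numeric(values))),
                 scale = scale, variant = variant),
            class = "temp_config")
}

#' Predict the early and late phenotypes for one year
#'
#' With deviations `dE = E - Ebar`, `dL = L - Lbar`:
#' \deqn{\hat E_t = \bar E + m_{EE} dE_{t-1} + m_{LE} dL_{t-1}}
#' \deqn{\hat L_t = \bar L + m_{EL} dE_{t-1} + m_{LL} dL_{t-1} + w\, dE_t}
#'
#' @param seasonal A [seasonal_series()].
#' @param strategy A [temp_strategy()].
#' @param t Year index (>= 2).
#' @return Named numeric vector `c(early = ..., late = ...)`.
#' @export
predict_season_phenotypes <- function(seasonal, strategy, t) {
  stopifnot(inherits(seasonal, "seasonal_series"),
            inherits(strategy, "temp_strategy"))
  if (t < 2L || t > length(seasonal$years)) {
    stop("index error: t must have one prior year within the series",
         call. = FALSE)
  }
  dE <- seasonal$early$values - seasonal$early$baseline
  dL <- seasonal$late$values - seasonal$late$baseline
  eb <- seasonal$early$baseline; lb <- seasonal$late$baseline
  c(early = eb + strategy$m_ee * dE[t - 1L] + strategy$m_le * dL[t - 1L],
    late = lb + strategy$m_el * dE[t - 1L] + strategy$m_ll * dL[t - 1L] +
      strategy$w * dE[t])
}

temp_scales <- function(seasonal, config) {
  s <- if (config$scale == "mean") {
    c(seasonal$early$baseline, seasonal$late$baseline)
  } else {
    c(stats::sd(seasonal$early$values), stats::sd(seasonal$late$values))
  }
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("domain error: fitness scale must be > 0 (use scale = \"iasd\" ",
         "for series with non-positive means)", call. = FALSE)
  }
  s
}

#' Geometric-mean fitness of one temperature strategy
#'
#' Per-season fitness is `max(eps, 1 - |predicted - actual| / s)` with the
#' season's scale `s`; the geometric mean runs over all `2 * (n - 1)`
#' season-year observations (years 2..n, both seasons), in log space.
#'
#' @param seasonal A [seasonal_series()] of length >= 6.
#' @param strategy A [temp_strategy()].
#' @param config A [temp_config()].
#' @return A list with `strategy`, `gm_fitness`, `n_obs`.
#' @export
temp_geometric_mean_fitness <- function(seasonal, strategy,
                                        config = temp_config()) {
  stopifnot(inherits(seasonal, "seasonal_series"))
  n <- length(seasonal$years)
  if (n < 6L) stop("insufficient data: need at least 6 shared years",
                   call. = FALSE)
  s <- temp_scales(seasonal, config)
  dE <- seasonal$early$values - seasonal$early$baseline
  dL <- seasonal$late$values - seasonal$late$baseline
  idx <- 2:n
  errE <- strategy$m_ee * dE[idx - 1L] + strategy$m_le * dL[idx - 1L] - dE[idx]
  errL <- strategy$m_el * dE[idx - 1L] + strategy$m_ll * dL[idx - 1L] +
    strategy$w * dE[idx] - dL[idx]
  wE <- pmax(config$fitness_floor, 1 - abs(errE) / s[1L])
  wL <- pmax(config$fitness_floor, 1 - abs(errL) / s[2L])
  list(strategy = strategy,
       gm_fitness = exp(mean(log(c(wE, wL)))),
       n_obs = 2L * (n - 1L))
}

#' Optimise the temperature strategy grid at one site
#'
#' Evaluates the full factorial grid (vectorised: strategy-by-year error
#' matrices via matrix products), returns the optimum under a deterministic
#' parsimony tie-break (smallest total `|m_ee|+|m_el|+|m_le|+|m_ll|+|w|`,
#' then lexicographic), the full grid fitnesses, and the derived summaries
#' `total_tgp = (m_ee + m_el + m_le + m_ll) / 2`, `max_tgp` and `min_tgp`
#' (largest and smallest single transgenerational slope).
#'
#' @param seasonal A [seasonal_series()].
#' @param config A [temp_config()]; under `variant = "residual"` both
#'   seasons are linearly detrended first (means preserved).
#' @return A list of class `temp_landscape` with `grid` (strategy columns
#'   plus `gm_fitness`), `optimum` (one row plus summaries), `n_obs`,
#'   `variant`.
#' @export
evaluate_temp_landscape <- function(seasonal, config = temp_config()) {
  stopifnot(inherits(seasonal, "seasonal_series"),
            inherits(config, "temp_config"))
  if (config$variant == "residual") {
    seasonal <- seasonal_series(detrend_linear(seasonal$early)$series,
                                detrend_linear(seasonal$late)$series)
  }
  n <- length(seasonal$years)
  if (n < 6L) stop("insufficient data: need at least 6 shared years",
                   call. = FALSE)
  s <- temp_scales(seasonal, config)
  grid <- temp_strategy_grid(config$values)
  dE <- seasonal$early$values - seasonal$early$baseline
  dL <- seasonal$late$values - seasonal$late$baseline
  idx <- 2:n
  cues <- rbind(dE[idx - 1L], dL[idx - 1L])          # 2 x (n-1)
  ME <- as.matrix(grid[, c("m_ee", "m_le")])         # S x 2
  ML <- as.matrix(grid[, c("m_el", "m_ll")])
  nr <- nrow(grid)
  errE <- ME %*% cues - rep(dE[idx], each = nr)
  lsum <- rowSums(log(pmax(1 - abs(errE) / s[1L], config$fitness_floor)))
  errE <- ML %*% cues + outer(grid$w, dE[idx]) - rep(dL[idx], each = nr)
  lsum <- lsum +
    rowSums(log(pmax(1 - abs(errE) / s[2L], config$fitness_floor)))
  grid$gm_fitness <- exp(lsum / (2 * (n - 1L)))
  best <- grid$gm_fitness >= max(grid$gm_fitness) - 1e-12
  cand <- grid[best, , drop = FALSE]
  tot <- abs(cand$m_ee) + abs(cand$m_el) + abs(cand$m_le) + abs(cand$m_ll) +
    abs(cand$w)
  ord <- order(tot, cand$m_ee, cand$m_el, cand$m_le, cand$m_ll, cand$w)
  opt <- cand[ord[1L], , drop = FALSE]
  opt$total_tgp <- (opt$m_ee + opt$m_el + opt$m_le + opt$m_ll) / 2
  opt$max_tgp <- max(opt$m_ee, opt$m_el, opt$m_le, opt$m_ll)
  opt$min_tgp <- min(opt$m_ee, opt$m_el, opt$m_le, opt$m_ll)
  rownames(opt) <- NULL
  structure(list(grid = grid, optimum = opt, n_obs = 2L * (n - 1L),
                 variant = config$variant),
            class = "temp_landscape")
}
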