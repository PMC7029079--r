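#' A precipitation plasticity genotype
#'
#' A strategy is a linear transgenerational reaction norm on hydrologic-year
#' precipitation: `m` in \[-1, 1\] weights the (persistence-weighted)
#' deviation of recent years from the long-term mean, and `g` in \[0, 1\]
#' controls how strongly the grandparental (weight g) and great-grandparental
#' (weight g^2) years contribute relative to the parental year.  When
#' `m = 0` the phenotype is the long-term mean regardless of `g`, so the
#' canonical form fixes `g = 0` there.
#'
#' @param m Parental-effect slope in \[-1, 1\].
#' @param g Multigeneration persistence in \[0, 1\].
#' @return A list of class `precip_strategy` with elements `m`, `g`.
#' @export
precip_strategy <- function(m, g = 0) {
  if (!is.finite(m) || abs(m) > 1) stop("m must lie in [-1, 1]", call. = FALSE)
  if (!is.finite(g) || g < 0 || g > 1) stop("g must lie in [0, 1]", call. = FALSE)
  if (m == 0) g <- 0   # canonical form: g is inert at m = 0
  structure(list(m = m, g = g), class = "precip_strategy")
}

#' Model configuration for the precipitation grid search
#'
#' @param fitness_floor Floor epsilon applied to yearly fitness before the
#'   geometric mean (default 1e-6); keeps the geometric mean defined when
#'   the linear cost drops to or below zero.
#' @param m_grid Lattice of parental-effect values (default -1..1 by 0.1).
#' @param g_grid Lattice of persistence values (default 0..1 by 0.1).
#' @param variant `"raw"` (series as observed) or `"residual"` (linear
#'   trend removed, mean preserved, before optimisation).
#' @return A list of class `model_config`.
#' @export
model_config <- function(fitness_floor = 1e-6,
                         m_grid = seq(-1, 1, by = 0.1),
                         g_grid = seq(0, 1, by = 0.1),
                         variant = c("raw", "residual")) {
  variant <- match.arg(variant)
  if (!(fitness_floor > 0 && fitness_floor < 0.1)) {
    stop("fitness_floor must lie in (0, 0.1)", call. = FALSE)
  }
  stopifnot(length(m_grid) > 0L, length(g_grid) > 0L,
            !is.unsorted(m_grid), !is.unsorted(g_grid))
  structure(list(fitness_floor = fitness_floor,
                 m_grid = round(as.numeric(m_grid), 10),
                 g_grid = round(as.numeric(g_grid), 10),
                 variant = variant),
            class = "model_config")
}

# persistence-weighted mean deviation of the three prior years, for years
# t = 4..n (vectorised); d = deviations from baseline
weighted_history <- function(d, g) {
  n <- length(d)
  idx <- 4:n
  (d[idx - 1L] + g * d[idx - 2L] + g^2 * d[idx - 3L]) / (1 + g + g^2)
}

#' Predict the precipitation phenotype for one year
#'
#' The phenotype ("expected precipitation") is
#' \deqn{\hat P_t = \bar P + m \frac{d_{t-1} + g d_{t-2} + g^2 d_{t-3}}
#'   {1 + g + g^2}, \qquad d_k = P_k - \bar P.}
#' At `g = 0` this collapses to the single-generation parental-effect model
#' \eqn{\hat P_t = \bar P + m (P_{t-1} - \bar P)}; at `g = 1` the three
#' prior years contribute equally; the normalisation keeps `m = 1` meaning
#' "match the weighted past exactly".
#'
#' @param series An [annual_series()].
#' @param strategy A [precip_strategy()].
#' @param t Year index (1-based within the series); must be >= 4 so a full
#'   three-year history exists.
#' @return The predicted phenotype (same units as the series).
#' @export
predict_precip_phenotype <- function(series, strategy, t) {
  stopifnot(inherits(series, "annual_series"),
            inherits(strategy, "precip_strategy"))
  if (t < 4L || t > length(series$values)) {
    stop("index error: t must have three prior years within the series",
         call. = FALSE)
  }
  d <- series$values - series$baseline
  g <- strategy$g
  w <- (d[t - 1L] + g * d[t - 2L] + g^2 * d[t - 3L]) / (1 + g + g^2)
  series$baseline + strategy$m * w
}

#' Yearly fitness under the linear mismatch cost
#'
#' Fitness decreases linearly with the absolute distance between phenotype
#' and realised environment, scaled by the long-term mean:
#' `w = max(eps, 1 - |phenotype - actual| / baseline)`.
#'
#' @param phenotype Predicted value.
#' @param actual Realised value.
#' @param baseline Long-term mean (> 0); the scale of the cost.
#' @param eps Fitness floor.
#' @return Fitness in `[eps, 1]`.
#' @export
fitness_year <- function(phenotype, actual, baseline, eps = 1e-6) {
  if (any(baseline <= 0)) stop("domain error: baseline must be > 0",
                               call. = FALSE)
  pmax(eps, 1 - abs(phenotype - actual) / baseline)
}

#' Geometric-mean fitness of one precipitation strategy
#'
#' Usable years are those with a full three-year history (`n - 3` of `n`);
#' the geometric mean is computed in log space,
#' `W = exp(mean(log w_t))`, to avoid underflow across ~117 factors.
#'
#' @param series An [annual_series()] of length >= 8.
#' @param strategy A [precip_strategy()].
#' @param config A [model_config()]; only the floor is used here (the
#'   variant is applied by [evaluate_precip_landscape()]).
#' @return A list with `strategy`, `gm_fitness`, `n_years_used`.
#' @export
geometric_mean_fitness <- function(series, strategy, config = model_config()) {
  stopifnot(inherits(series, "annual_series"))
  n <- length(series$values)
  if (n < 8L) stop("insufficient data: need at least 8 years", call. = FALSE)
  d <- series$values - series$baseline
  pred <- series$baseline + strategy$m * weighted_history(d, strategy$g)
  w <- fitness_year(pred, series$values[4:n], series$baseline,
                    config$fitness_floor)
  list(strategy = strategy, gm_fitness = exp(mean(log(w))),
       n_years_used = n - 3L)
}

#' Geometric-mean fitness over the full (m, g) lattice
#'
#' Evaluates every lattice strategy (vectorised across the grid), locates
#' the global optimum with a deterministic parsimony tie-break (smallest
#' `|m|`, then smallest `g`, then lexicographic), and detects local maxima:
#' lattice points whose fitness is >= that of all 8-neighbourhood lattice
#' neighbours, with connected plateaus of equal fitness merged to a single
#' representative.  The `m = 0` column is flat in `g` by construction and
#' is reported as the single canonical point `(0, 0)`.
#'
#' @param series An [annual_series()].
#' @param config A [model_config()]; under `variant = "residual"` the
#'   series is first passed through [detrend_linear()].
#' @return A list of class `fitness_landscape` with elements `grid`
#'   (data.frame `m`, `g`, `gm_fitness` over the full lattice), `optimum`
#'   (row of `grid`), `local_maxima` (data.frame of representatives),
#'   `n_years_used`, `variant`.
#' @export
evaluate_precip_landscape <- function(series, config = model_config()) {
  stopifnot(inherits(series, "annual_series"), inherits(config, "model_config"))
  if (config$variant == "residual") series <- detrend_linear(series)$series
  n <- length(series$values)
  if (n < 8L) stop("insufficient data: need at least 8 years", call. = FALSE)
  d <- series$values - series$baseline
  actual <- series$values[4:n]
  mg <- config$m_grid; gg <- config$g_grid
  nm <- length(mg); ng <- length(gg)
  W <- matrix(NA_real_, nm, ng)   # rows m, cols g
  for (j in seq_len(ng)) {
    u <- weighted_history(d, gg[j])
    # errors for all m at once: |m * u - d_t|
    err <- abs(outer(mg, u) - rep(d[4:n], each = nm))
    lw <- log(pmax(1 - err / series$baseline, config$fitness_floor))
    W[, j] <- exp(rowMeans(lw))
  }
  grid <- data.frame(m = rep(mg, times = ng), g = rep(gg, each = nm),
                     gm_fitness = as.vector(W))
  optimum <- landscape_optimum(grid)
  lmax <- lattice_local_maxima(W, mg, gg)
  structure(list(grid = grid, optimum = optimum, local_maxima = lmax,
                 n_years_used = n - 3L, variant = config$variant),
            class = "fitness_landscape")
}

# argmax with parsimony tie-break: max W, then min |m|, then min g, then (m, g)
landscape_optimum <- function(grid) {
  best <- grid$gm_fitness >= max(grid$gm_fitness) - 1e-12
  cand <- grid[best, , drop = FALSE]
  ord <- order(abs(cand$m), cand$g, cand$m, cand$g)
  res <- cand[ord[1L], , drop = FALSE]
  if (res$m == 0) res$g <- 0   # canonical form
  rownames(res) <- NULL
  res
}

# local maxima on the (m, g) lattice of fitness matrix W (rows m, cols g):
# points >= all 8 neighbours, connected equal-fitness plateaus merged
lattice_local_maxima <- function(W, m_grid, g_grid, tol = 1e-12) {
  nm <- nrow(W); ng <- ncol(W)
  is_max <- matrix(TRUE, nm, ng)
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  for (s in seq_len(nrow(shifts))) {
    di <- shifts$di[s]; dj <- shifts$dj[s]
    ri <- seq_len(nm) + di; rj <- seq_len(ng) + dj
    ok_i <- ri >= 1L & ri <= nm; ok_j <- rj >= 1L & rj <= ng
    nb <- matrix(-Inf, nm, ng)
    nb[ok_i, ok_j] <- W[ri[ok_i], rj[ok_j]]
    is_max <- is_max & (W >= nb - tol)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(data.frame(m = numeric(0), g = numeric(0),
                                         gm_fitness = numeric(0)))
  # merge connected plateaus (8-neighbour adjacency + equal fitness)
  comp <- seq_len(nrow(idx))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(idx))) for (b in seq_len(nrow(idx))) {
      if (comp[a] != comp[b] &&
          abs(idx[a, 1] - idx[b, 1]) <= 1L &&
          abs(idx[a, 2] - idx[b, 2]) <= 1L &&
          abs(W[idx[a, 1], idx[a, 2]] - W[idx[b, 1], idx[b, 2]]) <= tol) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reps <- lapply(unique(comp), function(cc) {
    rows <- idx[comp == cc, , drop = FALSE]
    mm <- m_grid[rows[, 1]]; gg <- g_grid[rows[, 2]]
    ord <- order(abs(mm), gg, mm)
    data.frame(m = mm[ord[1L]], g = if (mm[ord[1L]] == 0) 0 else gg[ord[1L]],
               gm_fitness = W[rows[ord[1L], 1], rows[ord[1L], 2]])
  })
  out <- unique(do.call(rbind, reps))
  rownames(out) <- NULL
  out[order(out$m, out$g), , drop = FALSE]
}

#' Bimodality condition on the autocorrelation structure
#'
#' A site's (m, g) fitness landscape tends to carry two local optima with
#' opposing plasticity signs when the lag-1 autocorrelation points in a
#' different direction than the average of the lag-2 and lag-3 partial
#' autocorrelations, and is smaller than it in absolute value.
#'
#' @param summary A [site_summary()] row (or any list with `acf1`, `pacf2`,
#'   `pacf3`).
#' @return Logical.
#' @export
bimodality_condition <- function(summary) {
  a1 <- summary$acf1; p2 <- summary$pacf2; p3 <- summary$pacf3
  if (is.null(a1) || is.null(p2) || is.null(p3) ||
      anyNA(c(a1, p2, p3))) {
    stop("domain error: acf1, pacf2 and pacf3 are required", call. = FALSE)
  }
  avg <- mean(c(p2, p3))
  sign(a1) != sign(avg) && abs(a1) < abs(avg)
}
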