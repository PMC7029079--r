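#' Run configuration for batch pipelines
#'
#' @param input Path to a monthly climate CSV (see
#'   [read_monthly_climate()]).
#' @param model `"precip"` or `"temp"`.
#' @param variants Character vector, subset of `c("raw", "residual")`.
#' @param fitness_floor Yearly fitness floor.
#' @param m_grid,g_grid Precipitation lattices.
#' @param values Temperature parameter value set.
#' @param scale Temperature fitness scale, `"mean"` or `"iasd"`.
#' @param seed Seed for simulation subcommands.
#' @param out_dir Output directory for CLI runs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, model = c("precip", "temp"),
                       variants = c("raw", "residual"),
                       fitness_floor = 1e-6,
                       m_grid = seq(-1, 1, by = 0.1),
                       g_grid = seq(0, 1, by = 0.1),
                       values = default_temp_values(),
                       scale = "mean", seed = 1L, out_dir = ".") {
  model <- match.arg(model)
  variants <- match.arg(variants, c("raw", "residual"), several.ok = TRUE)
  structure(list(input = input, model = model, variants = variants,
                 fitness_floor = fitness_floor, m_grid = m_grid,
                 g_grid = g_grid, values = values, scale = scale,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

precip_site_result <- function(series, variant, config) {
  cfg <- model_config(fitness_floor = config$fitness_floor,
                      m_grid = config$m_grid, g_grid = config$g_grid,
                      variant = variant)
  ls <- evaluate_precip_landscape(series, cfg)
  sm <- site_summary(series)
  bim <- tryCatch(bimodality_condition(sm), error = function(e) NA)
  data.frame(site_id = series$site_id, model = "precip", variant = variant,
             m_opt = ls$optimum$m, g_opt = ls$optimum$g,
             gm_fitness = ls$optimum$gm_fitness, n_years = ls$n_years_used,
             n_local_maxima = nrow(ls$local_maxima),
             bimodal_condition = bim,
             mean = sm$mean, iasd = sm$iasd, trend_slope = sm$trend_slope,
             acf1 = sm$acf1, pacf2 = sm$pacf2, pacf3 = sm$pacf3,
             res_acf1 = sm$res_acf1,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

temp_site_result <- function(seasonal, variant, config) {
  cfg <- temp_config(fitness_floor = config$fitness_floor,
                     values = config$values, scale = config$scale,
                     variant = variant)
  ls <- evaluate_temp_landscape(seasonal, cfg)
  sm <- site_summary(seasonal)
  data.frame(site_id = seasonal$site_id, model = "temp", variant = variant,
             m_ee = ls$optimum$m_ee, m_el = ls$optimum$m_el,
             m_le = ls$optimum$m_le, m_ll = ls$optimum$m_ll,
             w = ls$optimum$w, gm_fitness = ls$optimum$gm_fitness,
             total_tgp = ls$optimum$total_tgp, max_tgp = ls$optimum$max_tgp,
             min_tgp = ls$optimum$min_tgp, n_obs = ls$n_obs,
             ee_acf = sm$ee_acf[1L], el_acf = sm$el_acf[1L],
             le_acf = sm$le_acf[1L], ll_acf = sm$ll_acf[1L],
             within_acf = sm$within_acf[1L],
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

skip_row <- function(site_id, model, reason) {
  data.frame(site_id = site_id, model = model, variant = NA_character_,
             skip_reason = reason, stringsAsFactors = FALSE)
}

#' Run the whole per-site pipeline over a monthly climate table
#'
#' For every site: aggregate the monthly table into annual (precipitation)
#' or seasonal (temperature) series, summarise the autocorrelation
#' structure, optimise the strategy grid under each requested variant, and
#' when both variants run, add `delta_*` columns (raw minus residual) per
#' optimum parameter.  Degenerate sites (constant series, too few complete
#' years) yield an in-band skip row with a reason instead of an error.
#' Sites are processed in sorted order, so output is deterministic.
#'
#' @param config A [run_config()].
#' @param table Optional pre-read `monthly_climate` table (skips the file
#'   read).
#' @return A `data.frame` with one row per site x variant plus skip rows.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) table <- read_monthly_climate(config$input)
  sites <- sort(unique(table$site_id))
  if (length(sites) == 0L) stop("domain error: empty site set", call. = FALSE)
  rows <- list()
  for (sid in sites) {
    res <- tryCatch({
      if (config$model == "precip") {
        series <- hydrologic_year_precip(table, sid)
        if (stats::sd(series$values) == 0) {
          stop("degenerate series: zero interannual variance", call. = FALSE)
        }
        do.call(rbind, lapply(config$variants, function(v)
          precip_site_result(series, v, config)))
      } else {
        seasonal <- season_tmax_pair(table, sid)
        if (stats::sd(seasonal$early$values) == 0 ||
            stats::sd(seasonal$late$values) == 0) {
          stop("degenerate series: zero interannual variance", call. = FALSE)
        }
        do.call(rbind, lapply(config$variants, function(v)
          temp_site_result(seasonal, v, config)))
      }
    }, error = function(e) skip_row(sid, config$model, conditionMessage(e)))
    rows[[sid]] <- res
  }
  out <- do.call(rbind_fill, rows)
  rownames(out) <- NULL
  if (length(config$variants) == 2L) out <- add_variant_deltas(out, config)
  out
}

# rbind data.frames with different column sets, filling with NA
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
    d[, cols, drop = FALSE]
  }))
}

add_variant_deltas <- function(out, config) {
  pars <- if (config$model == "precip") c("m_opt", "g_opt") else
    c("m_ee", "m_el", "m_le", "m_ll", "w")
  for (p in pars) out[[paste0("delta_", p)]] <- NA_real_
  for (sid in unique(out$site_id)) {
    r <- which(out$site_id == sid & out$variant %in% "raw")
    s <- which(out$site_id == sid & out$variant %in% "residual")
    if (length(r) == 1L && length(s) == 1L) {
      for (p in pars) {
        out[[paste0("delta_", p)]][c(r, s)] <- out[[p]][r] - out[[p]][s]
      }
    }
  }
  out
}

#' Histogram of optimal parameter values over the strategy grid
#'
#' @param results A [run_pipeline()] result table.
#' @param parameter Column to tabulate (`"m_opt"`, `"g_opt"`, `"m_ee"`,
#'   `"m_el"`, `"m_le"`, `"m_ll"`, `"w"`).
#' @param grid_values Lattice over which to count; defaults to the
#'   model's standard grid for the parameter.
#' @param variant Restrict to one variant (default: all rows).
#' @return A `data.frame` with `value` and `count`; counts sum to the
#'   number of contributing (non-skipped) rows.
#' @export
optima_histogram <- function(results, parameter, grid_values = NULL,
                             variant = NULL) {
  known <- c("m_opt", "g_opt", "m_ee", "m_el", "m_le", "m_ll", "w")
  if (!parameter %in% known || !parameter %in% names(results)) {
    stop("domain error: unknown parameter: ", parameter, call. = FALSE)
  }
  if (is.null(grid_values)) {
    grid_values <- switch(parameter,
      m_opt = seq(-1, 1, by = 0.1),
      g_opt = seq(0, 1, by = 0.1),
      default_temp_values())
  }
  rows <- results[!is.na(results[[parameter]]), , drop = FALSE]
  if (!is.null(variant)) rows <- rows[rows$variant == variant, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no usable results", call. = FALSE)
  vals <- round(rows[[parameter]], 10)
  grid_values <- round(grid_values, 10)
  counts <- vapply(grid_values, function(v) sum(vals == v), integer(1))
  if (sum(counts) != nrow(rows)) {
    stop("domain error: optima found off the supplied grid", call. = FALSE)
  }
  data.frame(value = grid_values, count = counts)
}

#' Regress temperature optima on the autocorrelation classes
#'
#' Ordinary least squares (with intercept) of each optimal
#' transgenerational slope (`m_ee`, `m_el`, `m_le`, `m_ll`) on the five
#' per-site correlation classes (`ee_acf`, `el_acf`, `le_acf`, `ll_acf`,
#' `within_acf`).  A positive "diagonal" (each slope loading most on its
#' own correlation class) indicates the optimiser recovers the structure
#' the climate actually carries.
#'
#' @param results A [run_pipeline()] result table with temperature rows.
#' @param variant Which variant's optima to use (default `"raw"`).
#' @return 5 x 4 numeric matrix: rows = predictors, cols = responses.
#' @export
regress_optima_on_acf <- function(results, variant = "raw") {
  preds <- c("ee_acf", "el_acf", "le_acf", "ll_acf", "within_acf")
  resp <- c("m_ee", "m_el", "m_le", "m_ll")
  rows <- results[results$model %in% "temp" & results$variant %in% variant &
                    !is.na(results$m_ee), , drop = FALSE]
  if (nrow(rows) < 10L) {
    stop("precondition error: need at least 10 temperature sites",
         call. = FALSE)
  }
  X <- as.matrix(rows[, preds])
  coefs <- matrix(NA_real_, length(preds), length(resp),
                  dimnames = list(preds, resp))
  for (r in resp) {
    fit <- stats::lm.fit(cbind(1, X), rows[[r]])
    b <- fit$coefficients[-1L]
    if (anyNA(b)) warning("rank-deficient design; missing coefficients for ", r)
    coefs[, r] <- b
  }
  coefs
}

#' Classify a precipitation strategy by sign and persistence
#'
#' Seven labels: `"none"` for (0, 0), otherwise the cross of the sign of
#' `m` (`positive` / `negative`) with the persistence regime of `g`
#' (`single-generation` for g = 0, `intermediate` for 0 < g < 1,
#' `full-persistence` for g = 1).
#'
#' @param m,g Strategy parameters on the standard grid.
#' @return A label string.
#' @export
classify_strategy <- function(m, g) {
  if (!is.finite(m) || !is.finite(g) || abs(m) > 1 || g < 0 || g > 1) {
    stop("domain error: (m, g) outside the strategy space", call. = FALSE)
  }
  if (m == 0) return("none")
  sgn <- if (m > 0) "positive" else "negative"
  per <- if (g == 0) "single-generation" else if (g == 1) "full-persistence"
         else "intermediate"
  paste(sgn, per, sep = "/")
}
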