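#' Annual climate series
#'
#' Container for one site's per-year values of a single climate variable:
#' hydrologic-year precipitation totals (mm), or early / late growing-season
#' mean daily maximum temperature (degrees C).  The `baseline` is the
#' long-term arithmetic mean across all years and serves as the "genetic"
#' component of phenotype in the optimality models.
#'
#' @param site_id Site identifier (scalar character).
#' @param variable One of `"precip"`, `"tmax_early"`, `"tmax_late"`.
#' @param years Integer vector of strictly increasing, contiguous year labels.
#' @param values Numeric vector, one value per year.
#'
#' @return An object of class `annual_series` with fields `site_id`,
#'   `variable`, `years`, `values` and `baseline` (recomputed mean).
#' @export
#' @examples
#' s <- annual_series("A", "precip", 2000:2009, rnorm(10, 700, 100))
#' s$baseline
annual_series <- function(site_id, variable, years, values) {
  variable <- match.arg(variable, c("precip", "tmax_early", "tmax_late"))
  stopifnot(is.character(site_id), length(site_id) == 1L)
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have equal length", call. = FALSE)
  }
  if (length(years) < 5L) {
    stop("insufficient data: an annual series needs at least 5 years",
         call. = FALSE)
  }
  if (any(diff(years) != 1L)) {
    stop("`years` must be strictly increasing and contiguous", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  structure(
    list(site_id = site_id, variable = variable, years = years,
         values = values, baseline = mean(values)),
    class = "annual_series"
  )
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> site %s, %s, %d years (%d-%d), baseline %.4g\n",
              x$site_id, x$variable, length(x$years), min(x$years),
              max(x$years), x$baseline))
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$values)

#' Paired early/late season temperature series
#'
#' Bundles the early (Mar-May) and late (Jul-Sep) growing-season temperature
#' series of one site over a shared, contiguous span of years.
#'
#' @param early `annual_series` with variable `"tmax_early"`.
#' @param late `annual_series` with variable `"tmax_late"`, same site and
#'   identical year labels.
#'
#' @return An object of class `seasonal_series` with fields `site_id`,
#'   `years`, `early`, `late`.
#' @export
seasonal_series <- function(early, late) {
  stopifnot(inherits(early, "annual_series"), inherits(late, "annual_series"))
  if (early$variable != "tmax_early" || late$variable != "tmax_late") {
    stop("`early`/`late` must carry variables tmax_early / tmax_late",
         call. = FALSE)
  }
  if (early$site_id != late$site_id) {
    stop("early and late series belong to different sites", call. = FALSE)
  }
  if (!identical(early$years, late$years)) {
    stop("early and late series must share identical year labels",
         call. = FALSE)
  }
  structure(
    list(site_id = early$site_id, years = early$years,
         early = early, late = late),
    class = "seasonal_series"
  )
}

#' @export
print.seasonal_series <- function(x, ...) {
  cat(sprintf("<seasonal_series> site %s, %d years (%d-%d), Ebar %.3f, Lbar %.3f\n",
              x$site_id, length(x$years), min(x$years), max(x$years),
              x$early$baseline, x$late$baseline))
  invisible(x)
}
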