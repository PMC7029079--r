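#' Read a long-format monthly climate table
#'
#' Expects a flat CSV with header
#' `site_id,lat,lon,year,month,ppt_mm,tmax_c` ("." decimal separator, empty
#' cell = missing).  Unparseable numeric cells are converted to missing and
#' counted; the count is attached as attribute `n_flagged` and reported via
#' a message.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of class `monthly_climate` with columns
#'   `site_id`, `lat`, `lon`, `year`, `month`, `ppt_mm`, `tmax_c`.
#' @export
read_monthly_climate <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = TRUE)
  required <- c("site_id", "lat", "lon", "year", "month", "ppt_mm", "tmax_c")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tab <- data.frame(
    site_id = as.character(raw$site_id),
    lat = num(raw$lat), lon = num(raw$lon),
    year = num(raw$year), month = num(raw$month),
    ppt_mm = num(raw$ppt_mm), tmax_c = num(raw$tmax_c),
    stringsAsFactors = FALSE
  )
  # unparseable = non-missing text that failed numeric conversion
  n_flagged <- sum(!is.na(raw$ppt_mm) & is.na(tab$ppt_mm)) +
    sum(!is.na(raw$tmax_c) & is.na(tab$tmax_c))
  if (anyNA(tab$year) || anyNA(tab$month)) {
    stop("format error: year/month must be integers in every row",
         call. = FALSE)
  }
  tab$year <- as.integer(tab$year)
  tab$month <- as.integer(tab$month)
  validate_monthly_climate(tab)
  if (n_flagged > 0) {
    message(n_flagged, " unparseable numeric cell(s) flagged as missing")
  }
  attr(tab, "n_flagged") <- n_flagged
  class(tab) <- c("monthly_climate", "data.frame")
  tab
}

validate_monthly_climate <- function(tab) {
  if (any(tab$month < 1L | tab$month > 12L)) {
    stop("format error: month outside 1..12", call. = FALSE)
  }
  key <- paste(tab$site_id, tab$year, tab$month, sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (site_id, year, month) records",
         call. = FALSE)
  }
  if (any(tab$ppt_mm < 0, na.rm = TRUE)) {
    stop("integrity error: negative precipitation", call. = FALSE)
  }
  invisible(tab)
}

#' Construct a monthly climate table in memory
#'
#' @param site_id,lat,lon,year,month,ppt_mm,tmax_c Column vectors (recycled
#'   where scalar).
#' @return A validated `monthly_climate` data frame.
#' @export
monthly_climate <- function(site_id, lat, lon, year, month,
                            ppt_mm = NA_real_, tmax_c = NA_real_) {
  tab <- data.frame(site_id = as.character(site_id),
                    lat = as.numeric(lat), lon = as.numeric(lon),
                    year = as.integer(year), month = as.integer(month),
                    ppt_mm = as.numeric(ppt_mm), tmax_c = as.numeric(tmax_c),
                    stringsAsFactors = FALSE)
  validate_monthly_climate(tab)
  class(tab) <- c("monthly_climate", "data.frame")
  tab
}

site_rows <- function(table, site_id) {
  rows <- table[table$site_id == site_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("lookup error: site not present: ", site_id, call. = FALSE)
  }
  rows
}

#' Hydrologic-year precipitation totals
#'
#' Totals monthly precipitation over the 12-month hydrologic year running
#' October through September, so that winter precipitation (snowpack) is
#' credited to the growing season it feeds.  The hydrologic year is labeled
#' by its ending calendar year: Oct 1895 - Sep 1896 becomes year 1896.
#' Years with any of the 12 window months missing are dropped (with a
#' message); at least 5 complete hydrologic years are required.
#'
#' @param table A `monthly_climate` table.
#' @param site_id Site to extract.
#' @return An [annual_series()] with variable `"precip"`.
#' @export
hydrologic_year_precip <- function(table, site_id) {
  rows <- site_rows(table, site_id)
  # hydrologic year label: Oct-Dec belong to the following calendar year
  hy <- ifelse(rows$month >= 10L, rows$year + 1L, rows$year)
  ok <- !is.na(rows$ppt_mm)
  counts <- tapply(ok, hy, sum)
  totals <- tapply(ifelse(ok, rows$ppt_mm, 0), hy, sum)
  complete <- !is.na(counts) & counts == 12L
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(site_id, ": dropped ", n_dropped,
            " hydrologic year(s) with missing months")
  }
  yrs <- as.integer(names(counts))[complete]
  vals <- as.numeric(totals[complete])
  # keep the longest contiguous run ending at the last complete year
  keep <- contiguous_tail(yrs)
  if (length(keep) < 5L) {
    stop("insufficient data: fewer than 5 complete hydrologic years for ",
         site_id, call. = FALSE)
  }
  annual_series(site_id, "precip", yrs[keep], vals[keep])
}

#' Seasonal mean daily-maximum temperature series
#'
#' Early season is March-May, late season July-September, both within a
#' single calendar year.  The annual value is the arithmetic mean of the
#' three monthly values; years missing any of the three months are dropped.
#'
#' @param table A `monthly_climate` table.
#' @param site_id Site to extract.
#' @param season `"early"` (Mar-May) or `"late"` (Jul-Sep).
#' @return An [annual_series()] with variable `"tmax_early"` or
#'   `"tmax_late"`.
#' @export
season_tmax_series <- function(table, site_id, season = c("early", "late")) {
  season <- match.arg(season)
  months <- if (season == "early") 3:5 else 7:9
  rows <- site_rows(table, site_id)
  rows <- rows[rows$month %in% months & !is.na(rows$tmax_c), , drop = FALSE]
  counts <- tapply(rep.int(1L, nrow(rows)), rows$year, sum)
  means <- tapply(rows$tmax_c, rows$year, mean)
  complete <- !is.na(counts) & counts == 3L
  if (any(!complete)) {
    message(site_id, ": dropped ", sum(!complete),
            " year(s) with incomplete ", season, " season")
  }
  yrs <- as.integer(names(counts))[complete]
  vals <- as.numeric(means[complete])
  keep <- contiguous_tail(yrs)
  if (length(keep) < 5L) {
    stop("insufficient data: fewer than 5 complete ", season,
         "-season years for ", site_id, call. = FALSE)
  }
  annual_series(site_id, paste0("tmax_", season), yrs[keep], vals[keep])
}

#' Both seasonal series of a site as a pair
#'
#' Convenience wrapper around [season_tmax_series()] restricting both
#' seasons to their shared contiguous years.
#'
#' @inheritParams season_tmax_series
#' @return A [seasonal_series()].
#' @export
season_tmax_pair <- function(table, site_id) {
  e <- season_tmax_series(table, site_id, "early")
  l <- season_tmax_series(table, site_id, "late")
  shared <- intersect(e$years, l$years)
  keep <- contiguous_tail(sort(shared))
  shared <- sort(shared)[keep]
  if (length(shared) < 5L) {
    stop("insufficient data: fewer than 5 shared seasonal years for ",
         site_id, call. = FALSE)
  }
  sub <- function(s, v) annual_series(s$site_id, v, shared,
                                      s$values[match(shared, s$years)])
  seasonal_series(sub(e, "tmax_early"), sub(l, "tmax_late"))
}

# indices of the longest contiguous run of sorted years ending at the last one
contiguous_tail <- function(yrs) {
  n <- length(yrs)
  if (n == 0L) return(integer(0))
  brk <- which(diff(yrs) != 1L)
  start <- if (length(brk)) max(brk) + 1L else 1L
  start:n
}

#' Write per-site annual series as long CSV
#'
#' @param series_list List of `annual_series` objects.
#' @param path Output CSV path (columns `site_id,variable,year,value`).
#' @export
write_annual_series_csv <- function(series_list, path) {
  if (inherits(series_list, "annual_series")) series_list <- list(series_list)
  out <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(site_id = s$site_id, variable = s$variable,
               year = s$years, value = s$values, stringsAsFactors = FALSE)
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
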