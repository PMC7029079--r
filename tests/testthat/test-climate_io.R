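make_constant_table <- function(years, ppt = 10, tmax = 15, site = "A") {
  grid <- expand.grid(month = 1:12, year = years)
  monthly_climate(site, 40, -100, grid$year, grid$month, ppt, tmax)
}

test_that("read_monthly_climate round-trips a written fixture and validates", {
  tab <- make_constant_table(2000:2001)
  path <- withr::local_tempfile(fileext = ".csv")
  write_monthly_climate(tab, path)
  back <- read_monthly_climate(path)
  expect_equal(nrow(back), 24L)
  expect_equal(back$ppt_mm, tab$ppt_mm)
  expect_equal(back$tmax_c, tab$tmax_c)

  # missing required column -> format error
  broken <- as.data.frame(tab)
  broken$month <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, path2, row.names = FALSE)
  expect_error(read_monthly_climate(path2), "missing required column")

  # duplicate (site, year, month) -> integrity error
  expect_error(monthly_climate("A", 0, 0, c(2000, 2000), c(1, 1), 5, 10),
               "duplicate")
  # unparseable numerics flagged as missing, not fatal
  txt <- "site_id,lat,lon,year,month,ppt_mm,tmax_c\nA,40,-100,2000,1,oops,12\n"
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt, path3)
  expect_message(out <- read_monthly_climate(path3), "1 unparseable")
  expect_true(is.na(out$ppt_mm[1]))
})

test_that("hydrologic-year totals follow the Oct-Sep window, labeled by end year", {
  tab <- make_constant_table(2000:2006)
  s <- suppressMessages(hydrologic_year_precip(tab, "A"))
  # first (2000) and trailing (2007) windows are incomplete and dropped;
  # Oct 2000-Sep 2001 is the first complete window, labeled 2001
  expect_equal(s$years, 2001:2006)
  expect_equal(s$values, rep(120, 6))
  expect_equal(s$baseline, 120)
  expect_error(hydrologic_year_precip(tab, "nope"), "lookup error")
})

test_that("incomplete hydrologic years are excluded and exclusion is local", {
  tab <- make_constant_table(2000:2010)
  s_full <- suppressMessages(hydrologic_year_precip(tab, "A"))
  # knock out one month early in the series: Aug 2002 sits in window 2002;
  # the series keeps the contiguous run of complete years after the gap
  tab2 <- tab[!(tab$year == 2002 & tab$month == 8), ]
  class(tab2) <- class(tab)
  expect_message(s <- hydrologic_year_precip(tab2, "A"), "dropped")
  expect_false(2002L %in% s$years)
  expect_equal(s$years, 2003:2010)
  # values of the years still present are unchanged
  shared <- intersect(s$years, s_full$years)
  expect_equal(s$values[match(shared, s$years)],
               s_full$values[match(shared, s_full$years)])
})

test_that("hydrologic totals match a brute-force window-sum oracle", {
  set.seed(11)
  grid <- expand.grid(month = 1:12, year = 1990:1999)
  tab <- monthly_climate("Z", 40, -100, grid$year, grid$month,
                         runif(nrow(grid), 0, 200), NA_real_)
  s <- hydrologic_year_precip(tab, "Z")
  oracle <- oracle_hydro_totals(tab, "Z")
  for (i in seq_along(s$years)) {
    expect_equal(s$values[i], oracle[[as.character(s$years[i])]],
                 tolerance = 1e-12)
  }
  # permutation invariance to row order
  perm <- tab[sample(nrow(tab)), ]
  class(perm) <- class(tab)
  expect_equal(hydrologic_year_precip(perm, "Z")$values, s$values)
})

test_that("seasonal tmax series average the right three months", {
  tab <- make_constant_table(2000:2009, tmax = NA)
  tab$tmax_c <- ifelse(tab$month %in% 3:5, c(10, 12, 14)[match(tab$month, 3:5)],
                       ifelse(tab$month %in% 7:9, 20, NA))
  class(tab) <- c("monthly_climate", "data.frame")
  e <- season_tmax_series(tab, "A", "early")
  expect_equal(e$values, rep(12, 10))
  l <- season_tmax_series(tab, "A", "late")
  expect_equal(l$values, rep(20, 10))

  # missing August drops that year from the late series only
  tab2 <- tab[!(tab$year == 2001 & tab$month == 8), ]
  class(tab2) <- class(tab)
  expect_message(l2 <- season_tmax_series(tab2, "A", "late"), "dropped")
  expect_false(2001L %in% l2$years)
  expect_equal(l2$years, 2002:2009)
  expect_equal(suppressMessages(season_tmax_series(tab2, "A", "early"))$years,
               e$years)
})

test_that("seasonal means match a brute-force per-year oracle", {
  set.seed(12)
  grid <- expand.grid(month = 1:12, year = 2000:2009)
  tab <- monthly_climate("Q", 40, -100, grid$year, grid$month, NA_real_,
                         rnorm(nrow(grid), 15, 5))
  for (season in c("early", "late")) {
    months <- if (season == "early") 3:5 else 7:9
    s <- season_tmax_series(tab, "Q", season)
    for (i in seq_along(s$years)) {
      sel <- tab$year == s$years[i] & tab$month %in% months
      expect_equal(s$values[i], mean(tab$tmax_c[sel]), tolerance = 1e-12)
    }
  }
})

test_that("disaggregate_to_monthly round-trips through the readers", {
  spec <- annual_sim_spec(12, 800, 120, pacf_targets = 0.2, seed = 5)
  annual <- simulate_annual_series(spec, "S1", "precip")
  tab <- disaggregate_to_monthly(annual, seed = 9)
  back <- hydrologic_year_precip(tab, "S1")
  expect_equal(back$years, annual$years)
  expect_equal(back$values, annual$values, tolerance = 1e-9)

  # through a file as well
  path <- withr::local_tempfile(fileext = ".csv")
  write_monthly_climate(tab, path)
  back2 <- hydrologic_year_precip(read_monthly_climate(path), "S1")
  expect_equal(back2$values, annual$values, tolerance = 1e-6)

  # seasonal conservation: Mar/Apr/May mean equals the annual value exactly
  e <- simulate_annual_series(annual_sim_spec(10, 12, 1, seed = 2),
                              "S2", "tmax_early")
  etab <- disaggregate_to_monthly(e, seed = 3)
  eback <- season_tmax_series(etab, "S2", "early")
  expect_equal(eback$values, e$values, tolerance = 1e-9)
})

test_that("series constructors enforce their invariants", {
  expect_error(annual_series("A", "precip", 2000:2003, 1:4), "at least 5")
  expect_error(annual_series("A", "precip", c(2000:2003, 2005), rep(1, 5)),
               "contiguous")
  e <- annual_series("A", "tmax_early", 2000:2009, rnorm(10))
  l_bad <- annual_series("A", "tmax_late", 2001:2010, rnorm(10))
  expect_error(seasonal_series(e, l_bad), "identical year labels")
})
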