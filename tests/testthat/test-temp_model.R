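mk_pair <- function(e_vals, l_vals, site = "A") {
  yrs <- seq_along(e_vals) + 1900L
  seasonal_series(annual_series(site, "tmax_early", yrs, e_vals),
                  annual_series(site, "tmax_late", yrs, l_vals))
}

test_that("the strategy grid is the full factorial over five parameters", {
  g <- temp_strategy_grid()
  expect_equal(nrow(g), 3125L)
  expect_equal(nrow(temp_strategy_grid(c(0, 0.5))), 32L)
  zero <- g[g$m_ee == 0 & g$m_el == 0 & g$m_le == 0 & g$m_ll == 0 & g$w == 0, ]
  expect_equal(nrow(zero), 1L)
  expect_error(temp_strategy_grid(numeric(0)), "domain error")
})

test_that("seasonal phenotypes follow the stated linear maps", {
  # Ebar = 10, Lbar = 21 by construction
  e <- c(10, 10, 10, 10, 11, 9)
  l <- c(21, 21, 21, 21, 22, 20)
  p <- mk_pair(e - mean(e) + 10, l - mean(l) + 21)
  expect_equal(p$early$baseline, 10)
  zero <- temp_strategy()
  expect_equal(predict_season_phenotypes(p, zero, 5),
               c(early = 10, late = 21))
  carry <- temp_strategy(m_ll = 1)
  # L[t-1] = Lbar + 1 at t = 6
  expect_equal(predict_season_phenotypes(p, carry, 6)[["late"]],
               p$late$values[5])
  # hand case: E[t-1]-Ebar = 1, L[t-1]-Lbar = 1, E[t]-Ebar = -1
  st <- temp_strategy(m_ee = 0.1, m_el = 0.1, m_le = 0.3, m_ll = 0.3, w = 0.1)
  got <- predict_season_phenotypes(p, st, 6)
  expect_equal(got[["early"]], 10 + 0.1 * 1 + 0.3 * 1, tolerance = 1e-12)
  expect_equal(got[["late"]], 21 + 0.1 * 1 + 0.3 * 1 + 0.1 * (-1),
               tolerance = 1e-12)
  expect_error(predict_season_phenotypes(p, zero, 1), "index error")
})

test_that("temperature geometric mean matches the naive oracle", {
  vals <- default_temp_values()
  for (i in 1:20) {
    p <- random_seasonal(10 + i * 2, seed = 300 + i)
    set.seed(700 + i)
    for (j in 1:10) {
      st <- do.call(temp_strategy, as.list(setNames(sample(vals, 5, TRUE),
        c("m_ee", "m_el", "m_le", "m_ll", "w"))))
      got <- temp_geometric_mean_fitness(p, st)
      expect_equal(got$gm_fitness, oracle_temp_gm(p, st), tolerance = 1e-12)
      expect_equal(got$n_obs, 2L * (length(p$years) - 1L))
    }
  }
})

test_that("constant seasonal series score 1 for every strategy", {
  p <- mk_pair(rep(10, 8), rep(21, 8))
  expect_equal(temp_geometric_mean_fitness(p, temp_strategy(0.3, -0.2, 0.5,
                                                            0.1, 0.3))$gm_fitness,
               1.0)
})

test_that("the landscape grid agrees with per-strategy evaluation", {
  p <- random_seasonal(30, seed = 77)
  ls <- evaluate_temp_landscape(p)
  set.seed(42)
  rows <- sample(nrow(ls$grid), 25)
  for (r in rows) {
    st <- do.call(temp_strategy, as.list(ls$grid[r, c("m_ee", "m_el", "m_le",
                                                      "m_ll", "w")]))
    expect_equal(ls$grid$gm_fitness[r],
                 temp_geometric_mean_fitness(p, st)$gm_fitness,
                 tolerance = 1e-12)
  }
  # derived summaries
  o <- ls$optimum
  expect_equal(o$total_tgp, (o$m_ee + o$m_el + o$m_le + o$m_ll) / 2)
  expect_equal(o$max_tgp, max(o$m_ee, o$m_el, o$m_le, o$m_ll))
})

test_that("strategy ranking is invariant under an E/L label swap", {
  # symmetric pair: swapping season labels with swapped parameters must
  # give the same fitness when the within term is off and scales match
  p <- random_seasonal(40, seed = 88)
  sym <- seasonal_series(
    annual_series("A", "tmax_early", p$years,
                  p$late$values - p$late$baseline + 15),
    annual_series("A", "tmax_late", p$years,
                  p$early$values - p$early$baseline + 15))
  st <- temp_strategy(m_ee = 0.3, m_el = 0.1, m_le = -0.2, m_ll = 0.5)
  swapped <- temp_strategy(m_ee = 0.5, m_el = -0.2, m_le = 0.1, m_ll = 0.3)
  orig <- seasonal_series(
    annual_series("A", "tmax_early", p$years,
                  p$early$values - p$early$baseline + 15),
    annual_series("A", "tmax_late", p$years,
                  p$late$values - p$late$baseline + 15))
  expect_equal(temp_geometric_mean_fitness(orig, st)$gm_fitness,
               temp_geometric_mean_fitness(sym, swapped)$gm_fitness,
               tolerance = 1e-12)
})

test_that("optimisation recovers the coupling class that generated the data", {
  # uncoupled white noise at n = 2000: the all-zero strategy wins most of
  # the time (sampling noise is below half a grid step there)
  zero_hits <- 0L
  for (seed in 1:10) {
    p <- simulate_seasonal_pair(seasonal_sim_spec(2000, seed = 800 + seed))
    o <- evaluate_temp_landscape(p)$optimum
    if (all(c(o$m_ee, o$m_el, o$m_le, o$m_ll, o$w) == 0)) {
      zero_hits <- zero_hits + 1L
    }
  }
  expect_gte(zero_hits, 6L)

  # LL-only coupling: m_ll positive, everything else small
  A <- matrix(c(0, 0, 0, 0.6), 2, 2, byrow = TRUE)
  ll_hits <- 0L
  for (seed in 1:5) {
    p <- simulate_seasonal_pair(seasonal_sim_spec(2000, var1_matrix = A,
                                                  seed = 900 + seed))
    o <- evaluate_temp_landscape(p)$optimum
    if (o$m_ll > 0 && all(abs(c(o$m_ee, o$m_el, o$m_le, o$w)) <= 0.1)) {
      ll_hits <- ll_hits + 1L
    }
  }
  expect_gte(ll_hits, 4L)

  # within-year innovation correlation only: w positive, m terms small
  w_hits <- 0L
  for (seed in 1:5) {
    p <- simulate_seasonal_pair(seasonal_sim_spec(2000,
                                                  within_year_corr = 0.6,
                                                  seed = 950 + seed))
    o <- evaluate_temp_landscape(p)$optimum
    if (o$w > 0 && all(abs(c(o$m_ee, o$m_el, o$m_le, o$m_ll)) <= 0.1)) {
      w_hits <- w_hits + 1L
    }
  }
  expect_gte(w_hits, 4L)
})
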