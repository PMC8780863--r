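test_that("position-to-time interpolates between the daily marks", {
  r <- race_tube_record(c(0, 40, 80))
  expect_equal(position_to_time(r, 20), 12)
  expect_equal(position_to_time(r, 40), 24)
  expect_equal(position_to_time(r, c(0, 80)), c(0, 48))
  r2 <- race_tube_record(c(0, 30, 70))
  expect_equal(position_to_time(r2, 50), 36) # 24 + 24*(50-30)/40
  expect_error(position_to_time(r, 90), "outside")
  expect_error(race_tube_record(c(0, 40, 30)), "increasing")
  expect_error(race_tube_record(c(0, 40), band_positions = 45), "within")
})

test_that("band periods read the growth time between adjacent bands", {
  # constant 2 mm/h growth, bands every 36 mm: an 18 h (LD9:9) read-out
  marks <- seq(0, 48 * 7, by = 48)
  bands <- seq(36, 48 * 7 - 1, by = 36)
  bp <- band_periods(race_tube_record(marks, bands))
  expect_true(bp$defined)
  expect_equal(bp$periods, rep(18, length(bands) - 1))
  # bands at two adjacent marks exactly
  bp24 <- band_periods(race_tube_record(marks, c(48, 96)))
  expect_equal(bp24$mean, 24)
  expect_false(band_periods(race_tube_record(marks, 36))$defined)
})

test_that("band periods are invariant to uniform rescaling of positions", {
  r <- gen_race_tube(period = 12, growth_speed = 1.5, days = 6,
                     jitter_sd = 0.3, seed = 5)
  r2 <- race_tube_record(r$mark_positions * 10, r$band_positions * 10)
  expect_equal(band_periods(r2)$periods, band_periods(r)$periods)
})

test_that("round trip recovers generator periods across regimes and seeds", {
  for (P in c(4, 6, 12, 18, 24)) {
    for (seed in 1:20) {
      r <- gen_race_tube(period = P, growth_speed = 1.5, days = 6,
                         jitter_sd = 0.03 * P, seed = seed)
      bp <- band_periods(r)
      expect_lt(abs(bp$mean - P) / P, 0.05)
    }
  }
})

test_that("growth rates, normalization and ratios behave as documented", {
  a <- race_tube_record(c(0, 40, 80))
  expect_equal(daily_growth(a), c(40, 40))
  expect_equal(relative_growth(a, a), 1)
  b <- race_tube_record(c(0, 20, 40))
  expect_equal(growth_ratio(a, b)$ratio, 2)
  # generator with DD speed 1.15x the LD12:12 speed
  ld <- gen_race_tube(24, growth_speed = 1.5, days = 6, jitter_sd = 0.1,
                      seed = 2)
  dd <- gen_race_tube(22, growth_speed = 1.5 * 1.15, days = 6,
                      jitter_sd = 0.1, seed = 3)
  expect_equal(relative_growth(dd, ld), 1.15, tolerance = 0.02)
})

test_that("the microconidium criterion is strict at 1.5", {
  expect_true(is_microconidium(3, 3))     # ratio 1.0
  expect_false(is_microconidium(3, 2))    # ratio exactly 1.5
  expect_false(is_microconidium(4.6, 3))
  m <- data.frame(length_um = c(rep(1.2, 30), rep(3, 70)),
                  width_um = rep(1, 100))
  expect_equal(microconidia_proportion(m), 0.30)
  expect_true(is.na(microconidia_proportion(m[0, ])))
  expect_error(is_microconidium(-1, 2), "positive")
})

test_that("correlation and t-test conventions match the reporting style", {
  x <- c(1.5, 3, 6, 12, 18, 24)
  cc <- condition_correlation(x, 2 * x + 1)
  expect_equal(cc$estimate, 1)
  expect_lt(cc$p_value, 0.001)
  flat <- condition_correlation(x, rep(2, 6))
  expect_false(flat$defined)
  expect_identical(significance_stars(c(0.03, 0.009, 5e-4, 0.2)),
                   c("*", "**", "***", "ns"))
  set.seed(1)
  tt <- two_sample_test(rnorm(6, 10, 0.2), rnorm(6, 12, 0.2))
  expect_lt(tt$p_value, 0.001)
  expect_identical(tt$stars, "***")
})

test_that("panel correlations: real effect detected, flat effect not", {
  hp <- c(0.75, 1, 2, 3, 6, 12)
  pan <- gen_condition_panel(hp, effect = "peaked", seed = 42)
  cc <- condition_correlation(pan$conditions$cycle_length,
                              pan$conditions$proportion)
  expect_lt(cc$p_value, 0.05)
  ns <- 0
  for (seed in 1:100) {
    pf <- gen_condition_panel(hp, effect = "flat", n_conidia = 150,
                              seed = seed)
    g <- condition_correlation(pf$conditions$cycle_length,
                               pf$conditions$mean_growth)
    if (g$p_value > 0.05) ns <- ns + 1
  }
  expect_gte(ns, 80)
})

test_that("race-tube and morphometry CSV dialects round-trip", {
  r <- gen_race_tube(18, 1.5, days = 6, jitter_sd = 0.2, seed = 9,
                     condition = "LD9:9")
  f <- tempfile(fileext = ".csv")
  write_race_tube(r, f)
  r2 <- read_race_tube(f)
  expect_equal(r2$mark_positions, r$mark_positions)
  expect_equal(r2$band_positions, r$band_positions)
  expect_identical(r2$condition, "LD9:9")
  m <- gen_morphometry(50, 0.4, seed = 1)
  f2 <- tempfile(fileext = ".csv")
  write.csv(m, f2, row.names = FALSE)
  expect_equal(read_morphometry(f2), m)
})
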