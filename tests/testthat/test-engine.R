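p18 <- get_parameter_set("PHR18", "control")

test_that("daily heat units use the capped mean-temperature form", {
  expect_equal(heat_units(30, 20, 10, 30), 15)
  expect_equal(heat_units(12, 4, 10, 30), 0)
  expect_equal(heat_units(40, 34, 10, 30), 20)  # mean 37 capped at tb - tg
})

test_that("temperature stress follows the sine response between base and optimum", {
  expect_equal(temperature_stress(30, 10, 30), 1)
  expect_equal(temperature_stress(10, 10, 30), 0)
  expect_equal(temperature_stress(20, 10, 30), sin(pi / 4))
  expect_equal(temperature_stress(50, 10, 30), 0)   # beyond the upper mirror
  expect_equal(temperature_stress(5, 10, 30), 0)
  expect_all_between(temperature_stress(seq(-10, 60, 0.5), 10, 30), 0, 1)
})

test_that("canopy interception is Beer's law on half of global radiation", {
  expect_equal(intercepted_par(20, 0), 0)
  expect_equal(intercepted_par(0, 3), 0)
  expect_equal(intercepted_par(20, 1e6), 10)  # full-closure asymptote
  expect_equal(intercepted_par(20, 2, 0.65), 0.5 * 20 * (1 - exp(-1.3)))
})

test_that("nitrogen dilution curve hits its anchors and stays monotone", {
  for (acc in c("PHR18", "PHR23")) for (cond in c("control", "heat")) {
    p <- get_parameter_set(acc, cond)
    expect_equal(optimal_n_fraction(0, p$bn1, p$bn2, p$bn3), p$bn1)
    expect_equal(optimal_n_fraction(1, p$bn1, p$bn2, p$bn3), p$bn3)
    mid <- optimal_n_fraction(0.5, p$bn1, p$bn2, p$bn3)
    expect_lt(abs(mid - p$bn2) / p$bn2, 0.10)
    vals <- optimal_n_fraction(seq(0, 1.2, 0.01), p$bn1, p$bn2, p$bn3)
    expect_true(all(diff(vals) <= 1e-12))
  }
  expect_error(optimal_n_fraction(0.5, 0.003, 0.007, 0.03), "nonincreasing")
})

test_that("single steps respond correctly to dark and cold days", {
  m <- unstressed_management(as.Date("2023-05-01"))
  st <- pepsim:::new_sim_state(m)
  st$lai <- 1; st$biomass <- 500; st$cum_hu <- 200
  dark <- list(tmax = 30, tmin = 30, srad = 0, precip = 0)
  st2 <- step_day(st, dark, p18, m)
  expect_equal(st2$biomass, st$biomass)
  cold <- list(tmax = 8, tmin = 2, srad = 15, precip = 0)
  st3 <- step_day(st, cold, p18, m)
  expect_equal(st3$cum_hu, st$cum_hu)
  expect_equal(st3$ts, 0)
  expect_equal(st3$biomass, st$biomass)  # REG = 0 blocks growth
})

test_that("an unstressed step gains exactly RUE times intercepted PAR", {
  m <- unstressed_management(as.Date("2023-05-01"))
  st <- pepsim:::new_sim_state(m)
  st$lai <- 2; st$biomass <- 1000; st$cum_hu <- 900; st$hui <- 0.5
  st$plant_n <- 1e5  # saturate the N pool so ns = 1
  day <- list(tmax = 42, tmin = 18, srad = 20, precip = 0)  # mean = optimum
  st2 <- step_day(st, day, p18, m)
  expect_equal(st2$reg, 1)
  expect_equal(st2$biomass - st$biomass,
               p18$wa * intercepted_par(20, st2$lai, p18$k_ext),
               tolerance = 1e-12)
})

test_that("a dark season yields nothing", {
  wx <- greenhouse_series(42, 18, n_days = 150, srad_mean = 0,
                          start = as.Date("2023-04-25"))
  sim <- run_season(p18, wx, unstressed_management(as.Date("2023-04-25")))
  expect_equal(sim$yield, 0)
  expect_equal(sim$final_biomass, 0)
})

test_that("unstressed season biomass equals RUE times summed interception", {
  wx <- optimal_series(150)
  sim <- run_season(p18, wx, unstressed_management(wx$date[1]))
  expect_true(all(sim$trajectory$reg == 1))
  oracle <- p18$wa * sum(sim$trajectory$ipar) / 1000
  expect_equal(sim$final_biomass, oracle, tolerance = 1e-9)
})

test_that("biomass is conserved: the trajectory re-sums to the final state", {
  wx <- synth_field_weather("korea-central", 2022, seed = 21)
  sim <- run_season(p18, wx, management(planting_date = as.Date("2022-04-25")))
  tr <- sim$trajectory
  resum <- sum(p18$wa * tr$ipar * tr$reg) / 1000
  expect_equal(sim$final_biomass, resum, tolerance = 1e-9)
  expect_true(all(diff(tr$biomass) >= 0))
})

test_that("stress factors stay within [0, 1] across stressed seasons", {
  for (seed in c(1, 8)) {
    wx <- synth_field_weather("korea-south", 2021, seed = seed)
    m <- management(planting_date = as.Date("2021-04-25"),
                    soil_capacity = 60, initial_soil_water = 30,
                    irrigation_trigger = 0.3, n_supply = 40)
    sim <- run_season(p18, wx, m)
    tr <- sim$trajectory
    expect_all_between(c(tr$ts, tr$ws, tr$ns), 0, 1)
    expect_equal(tr$reg, pmin(tr$ts, pmin(tr$ws, tr$ns)))
  }
})

test_that("leaf area is unimodal with decline starting at the configured stage", {
  wx <- synth_field_weather("korea-central", 2022, seed = 5)
  p <- get_parameter_set("PHR18", "control", "field")  # dlai = 0.9
  sim <- run_season(p, wx, management(planting_date = as.Date("2022-04-25")))
  tr <- sim$trajectory
  growth <- tr$hui <= p$dlai
  expect_true(all(diff(tr$lai[growth]) >= -1e-12))
  expect_true(all(diff(tr$lai[!growth]) <= 1e-12))
  expect_lt(tr$lai[nrow(tr)], max(tr$lai))
})

test_that("yield equals harvest index times biomass once mature", {
  wx <- optimal_series(200)
  sim <- run_season(p18, wx, unstressed_management(wx$date[1]))
  expect_true(sim$matured)
  expect_equal(sim$final_hui, 1)
  expect_equal(sim$yield / sim$final_biomass, p18$hi)
  expect_lte(sim$yield, sim$final_biomass)
})

test_that("warming advances maturity monotonically", {
  wx <- synth_field_weather("korea-central", 2023, seed = 31)
  m <- management(planting_date = as.Date("2023-04-25"))
  expect_equal(as.integer(maturity_shift(p18, wx, m, 0)), 0L)
  s3 <- maturity_shift(p18, wx, m, 3)
  s5 <- maturity_shift(p18, wx, m, 5)
  expect_gt(as.integer(s5), 0L)
  expect_gte(as.integer(s5), as.integer(s3))
})

test_that("degenerate weather inputs are rejected", {
  wx <- synth_field_weather("korea-central", 2023, seed = 1)
  m <- management(planting_date = as.Date("2023-12-25"))
  expect_error(run_season(p18, wx, m), "shorter than 10 days")
  m2 <- management(planting_date = as.Date("2025-01-01"))
  expect_error(run_season(p18, wx, m2), "cover")
})
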