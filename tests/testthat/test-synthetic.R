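test_that("noiseless trial observations lie exactly on the engine trajectory", {
  p <- get_parameter_set("PHR18", "control")
  wx <- greenhouse_series(28, 18, n_days = 77, seed = 1)
  zero_sd <- list(total_fresh_g = 0, fruit_fresh_g = 0, lai = 0, height_cm = 0,
                  stem_mm = 0, moisture_pct = 0, total_n_g = 0)
  des <- trial_design(replicates = 1, noise_sd = zero_sd, seed = 9)
  m <- management(planting_date = wx$date[1], density = 3,
                  initial_soil_water = 150, n_supply = 400)
  obs <- gen_trial(des, p, wx, m)
  sim <- run_season(p, wx, m)
  expect_equal(obs$lai, sim$trajectory$lai[obs$day])
  expect_equal(obs$total_fresh_g,
               sim$trajectory$biomass[obs$day] * 0.1 / 3 / (1 - 0.86))
  expect_true(all(obs$fruit_fresh_g <= obs$total_fresh_g))
})

test_that("trial generation is seed-deterministic and clamps to invariants", {
  p <- get_parameter_set("PHR23", "heat")
  wx <- greenhouse_series(30, 22, n_days = 77, seed = 2)
  a <- gen_trial(trial_design(seed = 42), p, wx)
  b <- gen_trial(trial_design(seed = 42), p, wx)
  expect_identical(a, b)
  for (s in 1:20) {
    obs <- gen_trial(trial_design(seed = s, replicates = 1), p, wx)
    expect_true(all(obs$fruit_fresh_g <= obs$total_fresh_g))
    expect_all_between(obs$moisture_pct, 0, 100)
    expect_true(all(obs$total_fresh_g >= 0 & obs$lai >= 0 & obs$total_n_g >= 0))
  }
})

test_that("trial designs cannot sample beyond the weather series", {
  p <- get_parameter_set("PHR18", "control")
  wx <- greenhouse_series(28, 18, n_days = 30, seed = 1)
  expect_error(gen_trial(trial_design(measurement_days = c(10, 50), seed = 1),
                         p, wx), "beyond")
})

test_that("titration generator inverts the total-N equation", {
  rec <- gen_titration(14.01, sample_mass = 1, hcl_normality = 0.1, blank = 0)
  expect_equal(do.call(kjeldahl_total_n, setNames(rec, c("ml_sample", "ml_blank",
                                                         "hcl_normality", "sample_mass"))),
               14.01, tolerance = 1e-9)
  expect_equal(gen_titration(0, blank = 0.7)$ml_sample, 0.7)
  # volume above blank is linear in sample mass
  v1 <- gen_titration(10, sample_mass = 1, blank = 0)$ml_sample
  v2 <- gen_titration(10, sample_mass = 2, blank = 0)$ml_sample
  expect_equal(v2, 2 * v1)
  # round trip across magnitudes and with nonzero blank
  for (tn in c(0.5, 3, 14.01, 40)) {
    r <- gen_titration(tn, sample_mass = 1.3, hcl_normality = 0.1, blank = 0.4)
    expect_equal(kjeldahl_total_n(r$ml_sample, r$ml_blank, r$hcl_normality,
                                  r$sample_mass), tn, tolerance = 1e-9)
  }
  a <- gen_titration(10, seed = 1, noise_sd_ml = 0.1)
  b <- gen_titration(10, seed = 2, noise_sd_ml = 0.1)
  expect_false(identical(a$ml_sample, b$ml_sample))
})

test_that("pseudo-measured site yields enable heat-unit recovery", {
  p <- get_parameter_set("PHR18", "control", "field")
  sites <- mini_sites()
  ys <- gen_site_yields(sites, true_phu = c(1500, 1800), p, noise_sd = 0, seed = 6)
  expect_true(all(ys$measured_yield > 0))
  expect_equal(ys$measured_yield, ys$simulated_yield)
  for (i in seq_along(sites)) {
    wx <- pepsim:::site_year_weather(sites[[i]], 1L, wx_seed = 6 + i)
    m <- sites[[i]]$management
    m$planting_date <- as.Date(paste0(format(wx$date[1], "%Y"), "-04-25"))
    est <- estimate_phu(p, wx, m, ys$measured_yield[i], search = c(1200, 3500, 50))
    expect_lte(abs(est - ys$true_phu[i]), 50)
  }
  noisy <- gen_site_yields(sites, c(1500, 1800), p, noise_sd = 0.5, seed = 6)
  expect_false(identical(noisy$measured_yield, ys$measured_yield))
})

test_that("trial-to-calibration round trip degrades gracefully with noise", {
  # the leaf-area-curve calibration presumes near-optimal growing conditions
  # (as in the fertigated calibration greenhouse): constant
  # optimal-temperature weather, unlimited water and N. The realized
  # season maximum is the operational estimate of the maximum LAI.
  p <- get_parameter_set("PHR18", "control", "field")
  wx <- optimal_series(200)
  m <- unstressed_management(wx$date[1])
  sim <- run_season(p, wx, m)
  # sampling grid through the season plus a final harvest at maturity
  days <- unique(c(seq(8, nrow(sim$trajectory) - 1, by = 6),
                   nrow(sim$trajectory)))
  default_sd <- trial_design()$noise_sd
  scale_sd <- function(f) lapply(default_sd, function(s) s * f)
  rel_err <- function(noise_factor, seed) {
    des <- trial_design(measurement_days = days, replicates = 1,
                        noise_sd = scale_sd(noise_factor), seed = seed)
    obs <- gen_trial(des, p, wx, m)
    # recover harvest index at the last (near-maturity) harvest
    last <- obs[obs$day == max(obs$day), ]
    hi_hat <- min(1, max(0.05, last$fruit_fresh_g / last$total_fresh_g))
    # recover the leaf-area curve from growth-phase observations,
    # normalized by the observed season maximum
    hui <- sim$trajectory$hui[obs$day]
    keep <- hui <= p$dlai
    dmla_obs <- max(obs$lai)
    fit <- tryCatch(fit_lai_curve(hui[keep], pmin(obs$lai[keep], dmla_obs),
                                  dmla_obs),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pp <- p
    pp$hi <- hi_hat
    pp$dlap1 <- fit$dlap1; pp$dlap2 <- fit$dlap2
    pp$dlap_pts <- list(decode_point_code(fit$dlap1, "percent"),
                        decode_point_code(fit$dlap2, "percent"))
    pp$lai_curve <- solve_scurve(pp$dlap_pts[[1]], pp$dlap_pts[[2]])
    abs(run_season(pp, wx, m)$yield - sim$yield) / sim$yield
  }
  err0 <- rel_err(0, 1)
  err_half <- median(vapply(1:6, function(s) rel_err(0.5, s), numeric(1)), na.rm = TRUE)
  err_full <- median(vapply(1:6, function(s) rel_err(1, s), numeric(1)), na.rm = TRUE)
  expect_lt(err0, 0.03)       # only point-code rounding survives at zero noise
  expect_lt(err_half, 0.25)
  expect_lt(err_full, 0.35)
  expect_lte(err0, err_half + 1e-9)
})
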