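test_that("total-N titration arithmetic is exact and linear", {
  expect_equal(kjeldahl_total_n(100, 0, 0.1, 1), 14.01)
  expect_equal(kjeldahl_total_n(100, 0, 0.1, 2), 7.005)
  expect_equal(kjeldahl_total_n(10, 0, 0.1, 1), 1.401)
  expect_equal(kjeldahl_total_n(5, 5, 0.1, 1), 0)
  # linear in the net volume and in normality
  base <- kjeldahl_total_n(4, 1, 0.1, 1)
  expect_equal(kjeldahl_total_n(7, 1, 0.1, 1), 2 * base)
  expect_equal(kjeldahl_total_n(4, 1, 0.2, 1), 2 * base)
  expect_error(kjeldahl_total_n(10, 0, 0.1, 0), "positive")
  expect_error(kjeldahl_total_n(2, 5, 0.1, 1), "fault")
})

test_that("harvest index reproduces all tabulated greenhouse cells", {
  expect_equal(harvest_index(91, 326), 0.28)
  expect_equal(harvest_index(513, 950), 0.54)
  expect_equal(harvest_index(0, 100), 0)
  gh <- greenhouse_yield_summary()
  expect_equal(harvest_index(gh$fruit_fresh_g, gh$total_fresh_g),
               gh$harvest_index)
  expect_error(harvest_index(1, 0), "positive")
  expect_error(harvest_index(5, 3), "<=")
})

test_that("leaf-area curve fitting recovers generating codes from noiseless data", {
  cf <- solve_scurve(decode_point_code(10.19, "percent"),
                     decode_point_code(50.95, "percent"))
  x <- seq(0.05, 0.90, by = 0.05)  # includes the 10% anchor
  dmla <- 3.8
  lai <- dmla * scurve_eval(x, cf)
  fit <- fit_lai_curve(x, lai, dmla)
  expect_equal(fit$dlap1, 10.19, tolerance = 1e-9)
  expect_equal(fit$dlap2, 50.95, tolerance = 1e-9)
  # and for the widest packaged curve
  cf2 <- solve_scurve(decode_point_code(10.19, "percent"),
                      decode_point_code(65.95, "percent"))
  lai2 <- 6.1 * scurve_eval(x, cf2)
  fit2 <- fit_lai_curve(x, lai2, 6.1)
  expect_equal(fit2$dlap2, 65.95, tolerance = 1e-9)
})

test_that("leaf-area curve fitting rejects unusable inputs", {
  expect_error(fit_lai_curve(0.3, 1.5, 3.8), "2 usable")
  expect_error(fit_lai_curve(c(0.2, 0.4), c(1, 5), 3.8), "exceeds")
})

test_that("noisy leaf-area observations still localize the plateau anchor", {
  cf <- solve_scurve(decode_point_code(10.19, "percent"),
                     decode_point_code(50.95, "percent"))
  x <- seq(0.05, 0.90, by = 0.05)
  dmla <- 3.8
  err <- vapply(1:200, function(s) {
    set.seed(s)
    lai <- pmax(0, pmin(dmla, dmla * scurve_eval(x, cf) + rnorm(length(x), 0, 0.2)))
    fit <- tryCatch(fit_lai_curve(x, lai, dmla), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(floor(fit$dlap2) - 50)
  }, numeric(1))
  expect_lt(median(err, na.rm = TRUE), 5)
})

test_that("nitrogen fractions are read off the stages nearest midseason and maturity", {
  # synthetic plant with known fractions 0.006 and 0.003
  hui <- c(0.3, 0.55, 0.97)
  biomass <- c(200, 800, 1600)
  total_n <- c(0.01 * 200, 0.006 * 800, 0.003 * 1600)
  bn <- estimate_bn(total_n, biomass, hui)
  expect_equal(unname(bn["bn2"]), 0.006)
  expect_equal(unname(bn["bn3"]), 0.003)
  expect_equal(unname(estimate_bn(c(0, 0), c(100, 100), c(0.5, 1))["bn2"]), 0)
  expect_error(estimate_bn(c(1, 2), c(100, 100), c(0.9, 0.5)), "out of order")
  expect_error(estimate_bn(c(1, 2), c(100, 0), c(0.5, 1)), "biomass")
  expect_error(estimate_bn(1, 100, 0.5), "2 stages")
})

test_that("heat-unit requirement is recovered from an engine-generated yield", {
  p <- get_parameter_set("PHR18", "control", "field")
  wx <- synth_field_weather("korea-central", 2022, seed = 14)
  m <- management(planting_date = as.Date("2022-04-25"))
  true_phu <- 1800
  pp <- p; pp$phu <- true_phu
  target <- run_season(pp, wx, m)$yield
  est <- estimate_phu(p, wx, m, target, search = c(1200, 3500, 50))
  expect_lte(abs(est - true_phu), 50)
  expect_error(estimate_phu(p, wx, m, 8, search = c(2000, 1000, 50)), "malformed")
})

test_that("PHU grid ties break toward the smaller candidate", {
  p <- get_parameter_set("PHR18", "control", "field")
  # a dark season yields zero for every candidate: all losses tie at zero
  wx <- greenhouse_series(42, 18, start = as.Date("2023-04-25"),
                          n_days = 200, srad_mean = 0)
  m <- unstressed_management(wx$date[1])
  est <- estimate_phu(p, wx, m, measured_yield = 0, search = c(1500, 2000, 100))
  expect_equal(est, 1500)
})

test_that("field RUE is recovered from an engine-generated yield", {
  p <- get_parameter_set("PHR18", "control", "field")
  wx <- synth_field_weather("korea-central", 2023, seed = 15)
  m <- management(planting_date = as.Date("2023-04-25"))
  target <- run_season(p, wx, m)$yield  # generated at WA = 27
  est <- estimate_wa_field(p, wx, m, target, search = c(15, 40, 1))
  expect_equal(est, 27)
  # monotonicity of yield in RUE across the grid
  ys <- vapply(c(20, 27, 34), function(w) {
    pp <- p; pp$wa <- w; run_season(pp, wx, m)$yield
  }, numeric(1))
  expect_true(all(diff(ys) > 0))
  expect_error(estimate_wa_field(p, wx, m, 8, search = c(40, 15, 1)), "malformed")
})

test_that("fresh-to-dry areal conversion follows the unit arithmetic", {
  expect_equal(fresh_to_dry_areal(1000, 90, 1), 1)
  expect_equal(fresh_to_dry_areal(500, 100, 2), 0)
  expect_equal(fresh_to_dry_areal(1000, 90, 2), 2 * fresh_to_dry_areal(1000, 90, 1))
  expect_error(fresh_to_dry_areal(100, 150, 1), "moisture")
})
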