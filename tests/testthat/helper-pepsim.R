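# Shared fixtures: built in code, no stored data.

# Management with effectively unlimited water and nitrogen and no
# auto-irrigation: isolates the radiation/temperature pathway.
unstressed_management <- function(planting_date) {
  management(planting_date = planting_date, density = 4,
             irrigation_trigger = 0, irrigation_depth = 0,
             soil_capacity = 1e6, initial_soil_water = 1e6, n_supply = 1e6)
}

# A constant optimal-temperature series: daily mean exactly at the growth
# optimum (30 C for the packaged sets), so the temperature stress factor is 1.
optimal_series <- function(n_days = 150, srad = 18,
                           start = as.Date("2023-04-25")) {
  greenhouse_series(day_set = 42, night_set = 18, start = start,
                    n_days = n_days, jitter_sd = 0, srad_mean = srad)
}

# Small two-site list for scenario tests.
mini_sites <- function() {
  list(site_spec("north", "GW", "NorthTown", 1500, "korea-north"),
       site_spec("south", "JN", "SouthTown", 1800, "korea-south"))
}

expect_all_between <- function(x, lo, hi) {
  expect_true(all(x >= lo & x <= hi))
}
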