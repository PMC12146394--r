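#' Greenhouse trial design
#'
#' Measurement schedule and noise model for generating synthetic trial
#' observations. Defaults follow the two-year greenhouse heat-stress trial
#' design: 77-day treatment with measurements on a dense early grid, three
#' replicates, and per-variable Gaussian dispersion of the magnitude seen in
#' the packaged trial summary tables (those printed plus-minus values are
#' interpreted as standard deviations; the source tables do not distinguish
#' sd from se, which is documented here once and assumed throughout).
#'
#' @param measurement_days Days after treatment start on which observations
#'   are taken.
#' @param replicates Replicates per measurement day (>= 1).
#' @param noise_sd Named list of Gaussian sds:
#'   \code{total_fresh_g, fruit_fresh_g, lai, height_cm, stem_mm,
#'   moisture_pct, total_n_g}. Set all to 0 for noiseless observations.
#' @param seed Integer seed.
#' @return An object of class \code{"trial_design"}.
#' @export
trial_design <- function(measurement_days = c(1, 3, 5, 7, 9, 13, 15, 17, 19,
                                              21, 23, 25, 37, 49, 63, 77),
                         replicates = 3,
                         noise_sd = list(total_fresh_g = 250, fruit_fresh_g = 130,
                                         lai = 0.6, height_cm = 15, stem_mm = 2.5,
                                         moisture_pct = 2, total_n_g = 0.15),
                         seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(unlist(noise_sd) < 0)) stop("noise sds must be non-negative")
  structure(list(measurement_days = sort(measurement_days),
                 replicates = replicates, noise_sd = noise_sd, seed = seed),
            class = "trial_design")
}

#' Generate synthetic trial observations from an engine trajectory
#'
#' Runs the growth engine under the given parameter set and weather, samples
#' the trajectory at the design's measurement days, converts to per-plant
#' observables (fresh masses via an assumed moisture content, total N from
#' plant N), adds seeded Gaussian noise, and clamps to physical invariants
#' (fruit <= total, moisture in \[0, 100\], non-negative masses).
#'
#' @param design A [trial_design()].
#' @param p A [crop_params()] object.
#' @param wx A [weather_series()] covering all measurement days.
#' @param m A [management()] object (defaults to greenhouse-style unlimited
#'   water and N at the design's density).
#' @param moisture_mean Mean tissue moisture, percent of fresh mass.
#' @return data.frame of observations: accession, condition, day, replicate,
#'   total_fresh_g, fruit_fresh_g, lai, height_cm, stem_mm, moisture_pct,
#'   total_n_g.
#' @export
gen_trial <- function(design, p, wx, m = NULL, moisture_mean = 86) {
  stopifnot(inherits(design, "trial_design"))
  if (is.null(m))
    m <- management(planting_date = wx$date[1], density = 3,
                    irrigation_trigger = 0.8, soil_capacity = 150,
                    initial_soil_water = 150, n_supply = 400)
  if (max(design$measurement_days) > nrow(as.data.frame(wx)))
    stop("design day beyond the weather series")
  sim <- run_season(p, wx, m)
  tr <- sim$trajectory
  if (max(design$measurement_days) > nrow(tr))
    stop("design day beyond the simulated season (crop matured earlier)")
  rng <- local_rng(design$seed)
  sd <- design$noise_sd
  rows <- list()
  for (d in design$measurement_days) {
    st <- tr[d, ]
    dry_g_plant <- st$biomass * 0.1 / m$density       # kg ha-1 -> g plant-1
    hi_d <- realized_hi(st$hui, p)
    total_fresh <- dry_g_plant / (1 - moisture_mean / 100)
    fruit_fresh <- hi_d * total_fresh
    n_g_plant <- st$plant_n * 0.1 / m$density
    height <- 30 + 100 * st$hui                        # simple allometry, cm
    stem <- 8 + 12 * st$hui                            # mm
    for (r in seq_len(design$replicates)) {
      noise <- function(s) if (s > 0) rng$rnorm(1, 0, s) else 0
      tf <- max(0, total_fresh + noise(sd$total_fresh_g))
      ff <- min(tf, max(0, fruit_fresh + noise(sd$fruit_fresh_g)))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = p$accession, condition = p$condition, day = d,
        replicate = r,
        total_fresh_g = tf, fruit_fresh_g = ff,
        lai = max(0, st$lai + noise(sd$lai)),
        height_cm = max(0, height + noise(sd$height_cm)),
        stem_mm = max(0, stem + noise(sd$stem_mm)),
        moisture_pct = min(100, max(0, moisture_mean + noise(sd$moisture_pct))),
        total_n_g = max(0, n_g_plant + noise(sd$total_n_g)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic Kjeldahl titration record
#'
#' Inverts the total-N titration equation: given a true N content the
#' required sample titration volume is
#' \code{blank + true_n * 1000 * sample_mass / (normality * 14.01 * 100)},
#' plus optional Gaussian volume noise. [kjeldahl_total_n()] applied to a
#' noiseless record returns \code{true_n} exactly.
#'
#' @param true_n_g_per_kg True total N, g per kg sample (>= 0).
#' @param sample_mass Sample mass, g.
#' @param hcl_normality HCl normality.
#' @param blank Blank titration volume, mL.
#' @param seed Integer seed (only used when \code{noise_sd_ml > 0}).
#' @param noise_sd_ml Gaussian sd of the sample volume, mL.
#' @return List with \code{ml_sample, ml_blank, hcl_normality, sample_mass}.
#' @export
gen_titration <- function(true_n_g_per_kg, sample_mass = 1, hcl_normality = 0.1,
                          blank = 0.2, seed = 1L, noise_sd_ml = 0) {
  if (true_n_g_per_kg < 0) stop("true_n must be >= 0")
  if (sample_mass <= 0 || hcl_normality <= 0) stop("mass and normality must be positive")
  if (blank < 0) stop("blank volume must be >= 0")
  ml <- blank + true_n_g_per_kg * 1000 * sample_mass / (hcl_normality * 14.01 * 100)
  if (noise_sd_ml > 0) ml <- ml + local_rng(seed)$rnorm(1, 0, noise_sd_ml)
  if (ml < 0) stop("parameters imply a negative titration volume")
  list(ml_sample = ml, ml_blank = blank, hcl_normality = hcl_normality,
       sample_mass = sample_mass)
}

#' Generate engine-backed pseudo-measured site yields
#'
#' For each site, runs the engine at that site's true PHU and adds seeded
#' Gaussian noise to the simulated yield, producing a measured-yield record
#' suitable for testing [estimate_phu()] recovery.
#'
#' @param sites List of [site_spec()] objects.
#' @param true_phu Numeric vector of true PHU per site (recycled if length
#'   1).
#' @param p A [crop_params()] object (field setting recommended).
#' @param noise_sd Gaussian sd added to the yield, Mg ha-1.
#' @param seed Integer seed (weather and noise both derive from it).
#' @param year Calendar year of the generated weather.
#' @return data.frame: site, province, year, true_phu, measured_yield,
#'   simulated_yield (the noiseless engine value).
#' @export
gen_site_yields <- function(sites, true_phu, p, noise_sd = 0, seed = 1L,
                            year = 2023L) {
  true_phu <- rep_len(true_phu, length(sites))
  rng <- local_rng(seed)
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    wx <- site_year_weather(s, 1L, wx_seed = seed + i)
    m <- s$management
    m$planting_date <- as.Date(paste0(format(wx$date[1], "%Y"), "-04-25"))
    pp <- p; pp$phu <- true_phu[i]
    sim <- run_season(pp, wx, m)
    meas <- sim$yield + if (noise_sd > 0) rng$rnorm(1, 0, noise_sd) else 0
    data.frame(site = s$site, province = s$province, year = year,
               true_phu = true_phu[i], measured_yield = max(meas, 1e-6),
               simulated_yield = sim$yield, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
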