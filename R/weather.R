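#' Weather series container
#'
#' A `weather_series` is a data.frame with columns `date` (Date, strictly
#' increasing, no gaps), `tmax`, `tmin` (deg C), `srad` (MJ m-2 day-1 global
#' solar radiation) and `precip` (mm), plus `site` and `provenance`
#' attributes. All generators and readers return this class.
#'
#' @param df data.frame with the five columns above.
#' @param site Site label.
#' @param provenance One of \code{"observed"}, \code{"greenhouse-synthetic"},
#'   \code{"field-synthetic"}, \code{"perturbed"}.
#' @return A \code{weather_series}.
#' @export
weather_series <- function(df, site = "unknown", provenance = "observed") {
  need <- c("date", "tmax", "tmin", "srad", "precip")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing weather column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$date <- as.Date(df$date)
  validate_weather(df)
  structure(df, class = c("weather_series", "data.frame"),
            site = site, provenance = provenance)
}

validate_weather <- function(df) {
  if (nrow(df) == 0) stop("weather series is empty")
  bad <- which(df$tmax < df$tmin)
  if (length(bad)) stop("tmax < tmin at row ", bad[1], " (", df$date[bad[1]], ")")
  if (any(df$srad < 0)) stop("negative solar radiation")
  if (any(df$precip < 0)) stop("negative precipitation")
  dd <- diff(as.integer(df$date))
  if (any(dd <= 0)) stop("dates not strictly increasing at row ", which(dd <= 0)[1] + 1L)
  if (any(dd != 1)) stop("date gap at row ", which(dd != 1)[1] + 1L)
  invisible(df)
}

#' Greenhouse setpoint weather series
#'
#' Builds a daily series from day/night temperature setpoints, optionally
#' jittered, emulating a controlled-greenhouse regime (e.g. 28/18 deg C
#' control or 30/22 deg C heat treatment over a 77-day treatment period).
#'
#' @param day_set,night_set Daytime and nighttime setpoints, deg C
#'   (\code{day_set > night_set}).
#' @param start First date of the series.
#' @param n_days Number of days.
#' @param jitter_sd Gaussian sd (deg C) added independently to each day's
#'   tmax and tmin; 0 gives the setpoints exactly.
#' @param srad_mean Daily global radiation, MJ m-2 day-1 (constant).
#' @param seed Integer seed; same seed, same series.
#' @return A [weather_series()] with provenance "greenhouse-synthetic".
#' @export
greenhouse_series <- function(day_set, night_set, start = as.Date("2022-05-03"),
                              n_days = 77, jitter_sd = 0, srad_mean = 18,
                              seed = 1L) {
  if (day_set <= night_set) stop("day_set must exceed night_set")
  if (n_days < 1) stop("n_days must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  rng <- local_rng(seed)
  tmax <- day_set + if (jitter_sd > 0) rng$rnorm(n_days, 0, jitter_sd) else 0
  tmin <- night_set + if (jitter_sd > 0) rng$rnorm(n_days, 0, jitter_sd) else 0
  tmin <- pmin(tmin, tmax)  # truncate so tmax >= tmin
  weather_series(data.frame(date = start + seq_len(n_days) - 1L,
                            tmax = tmax, tmin = tmin,
                            srad = rep(srad_mean, n_days),
                            precip = 0),
                 site = "greenhouse", provenance = "greenhouse-synthetic")
}

#' Default climatology for the synthetic field-weather generator
#'
#' Seasonal-sinusoid parameters for three Korean-like latitude bands. The
#' temperature cycle peaks in late July/early August; a monsoon bump raises
#' wet-day probability and rainfall amounts in midsummer; radiation follows a
#' clear-sky seasonal curve damped on cloudy (wet) days.
#'
#' @param latitude_band \code{"korea-north"}, \code{"korea-central"} or
#'   \code{"korea-south"}.
#' @return A named list of generator parameters (all overridable through the
#'   \code{climatology} argument of [synth_field_weather()]).
#' @export
default_climatology <- function(latitude_band = "korea-central") {
  bands <- c("korea-central", "korea-north", "korea-south")
  if (!is.character(latitude_band) || !latitude_band[1] %in% bands)
    stop("unknown latitude_band '", latitude_band[1], "'; valid: ",
         paste(bands, collapse = ", "))
  latitude_band <- latitude_band[1]
  base <- list(
    peak_doy = 208,        # day-of-year of the warmest day
    diurnal_range = 9,     # mean tmax - tmin, deg C
    anomaly_sd = 2.5,      # sd of daily AR(1) temperature anomalies, deg C
    anomaly_rho = 0.65,    # AR(1) autocorrelation
    srad_summer = 24,      # clear-sky radiation at solstice, MJ m-2 d-1
    srad_winter = 9,
    cloud_factor_wet = 0.45,   # radiation multiplier on wet days
    cloud_factor_dry = 0.85,   # on dry days (haze/partial cloud)
    wet_prob_base = 0.22,      # off-monsoon wet-day probability
    wet_prob_monsoon = 0.55,   # at monsoon peak (doy ~ 195)
    monsoon_doy = 195,
    monsoon_width = 35,        # gaussian width of the monsoon bump, days
    rain_mean_base = 5,        # mean wet-day rainfall off-monsoon, mm
    rain_mean_monsoon = 18     # at monsoon peak, mm
  )
  band <- switch(latitude_band,
    "korea-north"   = list(tmax_peak = 28.0, tmax_trough = 0.5),
    "korea-central" = list(tmax_peak = 29.5, tmax_trough = 3.0),
    "korea-south"   = list(tmax_peak = 30.5, tmax_trough = 6.0))
  c(base, band, list(latitude_band = latitude_band))
}

#' Synthetic open-field daily weather
#'
#' Stochastic Korean-like weather: a sinusoidal annual mean-temperature
#' cycle plus AR(1) daily anomalies, radiation from a clear-sky seasonal
#' curve times a cloudiness factor, and precipitation as a seeded
#' occurrence/amount process with a midsummer monsoon bump. Intended to
#' drive the growth engine and the temperature-scenario machinery; it is a
#' statistical emulator, not a reanalysis product.
#'
#' @param latitude_band See [default_climatology()].
#' @param years Integer vector of calendar years to generate (full years).
#' @param seed Integer seed; same seed, same series.
#' @param climatology Optional named list overriding entries of
#'   [default_climatology()].
#' @return A [weather_series()] with provenance "field-synthetic".
#' @export
synth_field_weather <- function(latitude_band = "korea-central", years = 2023L,
                                seed = 1L, climatology = NULL) {
  if (length(years) == 0) stop("years must be non-empty")
  cl <- default_climatology(latitude_band)
  if (!is.null(climatology)) {
    unknown <- setdiff(names(climatology), names(cl))
    if (length(unknown)) stop("unknown climatology key(s): ",
                              paste(unknown, collapse = ", "))
    cl[names(climatology)] <- climatology
  }
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% years]
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  rng <- local_rng(seed)

  seas <- cos(2 * pi * (doy - cl$peak_doy) / 365.25)
  tmax_mean <- (cl$tmax_peak + cl$tmax_trough) / 2 +
    (cl$tmax_peak - cl$tmax_trough) / 2 * seas
  if (cl$anomaly_sd > 0) {
    innov <- rng$rnorm(n, 0, cl$anomaly_sd * sqrt(1 - cl$anomaly_rho^2))
    anom <- as.numeric(stats::filter(innov, cl$anomaly_rho, method = "recursive"))
  } else anom <- numeric(n)
  tmax <- tmax_mean + anom
  range_jit <- if (cl$anomaly_sd > 0) rng$rnorm(n, 0, 1) else numeric(n)
  tmin <- tmax - pmax(0.5, cl$diurnal_range + range_jit)

  # monsoon-modulated precipitation occurrence/amount process
  monsoon <- exp(-0.5 * ((doy - cl$monsoon_doy) / cl$monsoon_width)^2)
  p_wet <- cl$wet_prob_base + (cl$wet_prob_monsoon - cl$wet_prob_base) * monsoon
  wet <- rng$runif(n) < p_wet
  rain_mean <- cl$rain_mean_base + (cl$rain_mean_monsoon - cl$rain_mean_base) * monsoon
  precip <- ifelse(wet, rng$rgamma(n, shape = 0.9) * rain_mean / 0.9, 0)

  srad_clear <- cl$srad_winter + (cl$srad_summer - cl$srad_winter) *
    (1 + cos(2 * pi * (doy - 172) / 365.25)) / 2
  srad <- srad_clear * ifelse(wet, cl$cloud_factor_wet, cl$cloud_factor_dry)

  weather_series(data.frame(date = dates, tmax = tmax, tmin = tmin,
                            srad = srad, precip = precip),
                 site = cl$latitude_band, provenance = "field-synthetic")
}

#' Shift a weather series by a uniform temperature delta
#'
#' Adds \code{delta_t} to both daily maximum and minimum temperatures,
#' leaving radiation and precipitation unchanged — the standard delta-change
#' construction of warming scenarios (+3 to +5 deg C).
#'
#' @param series A [weather_series()].
#' @param delta_t Temperature increment, deg C.
#' @return A new series tagged \code{provenance = "perturbed"} (unless
#'   \code{delta_t == 0}, which returns the input unchanged).
#' @export
apply_delta <- function(series, delta_t) {
  stopifnot(inherits(series, "weather_series"))
  if (delta_t == 0) return(series)
  df <- as.data.frame(series)
  df$tmax <- df$tmax + delta_t
  df$tmin <- df$tmin + delta_t
  weather_series(df, site = attr(series, "site"), provenance = "perturbed")
}

#' Read / write weather CSV
#'
#' CSV dialect: header \code{date,tmax,tmin,srad,precip}, ISO-8601 dates,
#' \code{.} decimal separator, UTF-8. Lines starting with \code{#} are
#' provenance comments and are skipped on read.
#'
#' @param path File path.
#' @param site,provenance Metadata for the returned series.
#' @return A [weather_series()].
#' @export
read_weather_csv <- function(path, site = "unknown", provenance = "observed") {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("weather file is empty: ", path)
  weather_series(df, site = site, provenance = provenance)
}

#' @rdname read_weather_csv
#' @param series A [weather_series()] to write.
#' @param header_lines Optional character vector of \code{#}-prefixed
#'   provenance lines to prepend (see [provenance_header()]).
#' @export
write_weather_csv <- function(series, path, header_lines = NULL) {
  stopifnot(inherits(series, "weather_series"))
  df <- as.data.frame(series)
  df$tmax <- round(df$tmax, 2); df$tmin <- round(df$tmin, 2)
  df$srad <- round(df$srad, 2); df$precip <- round(df$precip, 2)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %d days, %s to %s (site: %s, %s)\n",
              nrow(x), min(x$date), max(x$date),
              attr(x, "site"), attr(x, "provenance")))
  NextMethod()
}

# Seeded RNG scoped to one generator call: no global .Random.seed leakage.
local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  env <- new.env()
  wrap <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
    if (is.null(env$state)) set.seed(as.integer(seed)) else
      assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    out
  }
  list(rnorm = wrap(stats::rnorm), runif = wrap(stats::runif),
       rgamma = wrap(stats::rgamma), sample_int = wrap(sample.int))
}
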