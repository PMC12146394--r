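#' Site specification for multi-site scenario runs
#'
#' @param site Short site id (used as table key).
#' @param province Province label.
#' @param city City label.
#' @param phu Site potential heat units, deg C day (> 0).
#' @param latitude_band Weather-generator band, see [default_climatology()];
#'   ignored when \code{weather_csv} is given.
#' @param weather_csv Optional path to an observed-weather CSV covering the
#'   simulated years; when NULL weather is generated synthetically.
#' @param management A [management()] object.
#' @return An object of class \code{"site_spec"}.
#' @export
site_spec <- function(site, province, city, phu,
                      latitude_band = "korea-central", weather_csv = NULL,
                      management = pepsim::management()) {
  if (phu <= 0) stop("phu must be positive")
  structure(list(site = site, province = province, city = city, phu = phu,
                 latitude_band = latitude_band, weather_csv = weather_csv,
                 management = management),
            class = "site_spec")
}

#' Default synthetic scenario sites
#'
#' Nine pepper-producing sites across seven Korean provinces with synthetic
#' per-site potential heat units following the regional gradient (lower in
#' the mountainous northeast, 1700-1800 in the west/central belt, highest in
#' the south). The PHU values are package-assigned stand-ins, not survey
#' estimates.
#'
#' @return A list of [site_spec()] objects.
#' @export
default_sites <- function() {
  def <- list(
    list("hoengseong", "GW", "Hoengseong", 1500, "korea-north"),
    list("anseong",    "GG", "Anseong",    1550, "korea-central"),
    list("jecheon",    "CB", "Jecheon",    1700, "korea-north"),
    list("dangjin",    "CN", "Dangjin",    1750, "korea-central"),
    list("cheongyang", "CN", "Cheongyang", 1750, "korea-central"),
    list("yeongyang",  "GB", "Yeongyang",  1600, "korea-north"),
    list("hamyang",    "GN", "Hamyang",    1800, "korea-south"),
    list("sinan",      "JN", "Sinan",      1800, "korea-south"),
    list("haenam",     "JN", "Haenam",     1800, "korea-south"))
  lapply(def, function(d) site_spec(d[[1]], d[[2]], d[[3]], d[[4]], d[[5]]))
}

#' Scenario specification
#'
#' @param delta_t Warming increments, deg C (all >= 0).
#' @param accessions Accessions to report (one table each).
#' @param baseline_condition Parameter-set condition for reference runs
#'   (default \code{"control"}).
#' @param perturbed_condition Condition for warmed runs (default
#'   \code{"heat"}: warmed crops follow the heat-calibrated parameter sets).
#' @param setting Parameter setting, normally \code{"field"} (field-adjusted
#'   radiation use efficiency and leaf-area decline onset).
#' @param n_years Number of synthetic weather years per site.
#' @return An object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(delta_t = c(3, 4, 5),
                          accessions = c("PHR18", "PHR23"),
                          baseline_condition = "control",
                          perturbed_condition = "heat",
                          setting = "field", n_years = 10) {
  if (any(delta_t < 0)) stop("delta_t values must be >= 0")
  structure(list(delta_t = delta_t, accessions = accessions,
                 baseline_condition = baseline_condition,
                 perturbed_condition = perturbed_condition,
                 setting = setting, n_years = n_years),
            class = "scenario_spec")
}

#' Run the multi-site warming-scenario experiment
#'
#' For every site and synthetic weather year: a baseline season with the
#' accession's baseline-condition field parameter set, and one warmed season
#' per temperature increment using the same weather shifted by delta and
#' the heat-condition field parameter set. The site PHU is held fixed
#' across deltas (the warming is applied to weather, not to the site's heat
#' requirement). Yields are averaged over years and reported per accession
#' as a [scenario_table()].
#'
#' @param sites List of [site_spec()] objects (default [default_sites()]).
#' @param spec A [scenario_spec()].
#' @param seed Integer master seed; per-site-year weather seeds are derived
#'   from it, so a given seed reproduces the report exactly.
#' @return An object of class \code{"scenario_run"}: list with
#'   \code{tables} (per accession), \code{details} (per-run records) and
#'   the inputs.
#' @export
run_scenarios <- function(sites = default_sites(), spec = scenario_spec(),
                          seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  rng <- local_rng(seed)
  wx_seeds <- matrix(rng$sample_int(2^30, length(sites) * spec$n_years),
                     nrow = length(sites))
  details <- list()
  tables <- list()
  site_ids <- vapply(sites, `[[`, "", "site")
  info <- data.frame(site = site_ids,
                     province = vapply(sites, `[[`, "", "province"),
                     city = vapply(sites, `[[`, "", "city"))
  for (acc in spec$accessions) {
    base_y <- matrix(NA_real_, nrow = length(sites), ncol = spec$n_years)
    pert_y <- array(NA_real_, c(length(sites), spec$n_years, length(spec$delta_t)))
    for (si in seq_along(sites)) {
      s <- sites[[si]]
      p_base <- get_parameter_set(acc, spec$baseline_condition, spec$setting)
      p_heat <- get_parameter_set(acc, spec$perturbed_condition, spec$setting)
      p_base$phu <- s$phu
      p_heat$phu <- s$phu
      for (yi in seq_len(spec$n_years)) {
        wx <- site_year_weather(s, yi, wx_seeds[si, yi])
        m <- s$management
        m$planting_date <- as.Date(paste0(format(wx$date[1], "%Y"), "-04-25"))
        res_b <- tryCatch(run_season(p_base, wx, m), error = function(e)
          stop("baseline run failed at site ", s$site, ", year index ", yi,
               ": ", conditionMessage(e)))
        base_y[si, yi] <- res_b$yield
        details[[length(details) + 1L]] <- run_record(acc, s, yi, 0, res_b)
        for (di in seq_along(spec$delta_t)) {
          dt <- spec$delta_t[di]
          res_p <- tryCatch(run_season(p_heat, apply_delta(wx, dt), m),
            error = function(e)
              stop("scenario run failed at site ", s$site, ", year index ",
                   yi, ", +", dt, "C: ", conditionMessage(e)))
          pert_y[si, yi, di] <- res_p$yield
          details[[length(details) + 1L]] <- run_record(acc, s, yi, dt, res_p)
        }
      }
    }
    baseline <- stats::setNames(rowMeans(base_y), site_ids)
    scen <- stats::setNames(
      lapply(seq_along(spec$delta_t),
             function(di) stats::setNames(rowMeans(pert_y[, , di, drop = FALSE],
                                                   dims = 1), site_ids)),
      paste0("+", spec$delta_t))
    tables[[acc]] <- scenario_table(baseline, scen, site_info = info)
  }
  structure(list(tables = tables, details = do.call(rbind, details),
                 spec = spec, seed = seed, sites = sites),
            class = "scenario_run")
}

site_year_weather <- function(s, year_index, wx_seed) {
  if (!is.null(s$weather_csv)) return(read_weather_csv(s$weather_csv, site = s$site))
  synth_field_weather(s$latitude_band, years = 2013L + year_index, seed = wx_seed)
}

run_record <- function(acc, s, yi, dt, res) {
  data.frame(accession = acc, site = s$site, year_index = yi, delta_t = dt,
             yield = res$yield, final_biomass = res$final_biomass,
             matured = res$matured,
             maturity_day = nrow(res$trajectory),
             total_irrigation = res$total_irrigation,
             w_stress_days = res$w_stress_days,
             n_stress_days = res$n_stress_days,
             stringsAsFactors = FALSE)
}

#' @export
print.scenario_run <- function(x, ...) {
  for (acc in names(x$tables)) {
    cat("Simulated mean yields (dry Mg ha-1), accession", acc, "\n")
    print(x$tables[[acc]])
    cat("\n")
  }
  invisible(x)
}

#' Stress-day summary of a scenario run
#'
#' Counts of days with water or nitrogen stress factor below 0.9, averaged
#' over years, per site and temperature increment.
#'
#' @param run A \code{scenario_run} from [run_scenarios()].
#' @return data.frame with columns accession, site, delta_t,
#'   \code{w_stress_days}, \code{n_stress_days}, \code{total_irrigation}
#'   (year means).
#' @export
stress_day_summary <- function(run) {
  stopifnot(inherits(run, "scenario_run"))
  d <- run$details
  agg <- stats::aggregate(d[, c("w_stress_days", "n_stress_days",
                                "total_irrigation")],
                          by = d[, c("accession", "site", "delta_t")], mean)
  agg[order(agg$accession, agg$site, agg$delta_t), ]
}
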