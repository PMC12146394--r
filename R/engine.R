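#' Management specification
#'
#' Cropping-management inputs of a season run: planting, stand density, the
#' soil-water bucket, automatic irrigation, and the season's plant-available
#' nitrogen supply (released pro-rata with development stage, mimicking
#' regular fertigation rather than a full soil N cycle).
#'
#' @param planting_date Date of planting/transplanting.
#' @param density Plants per square metre (> 0); open-field pepper stands
#'   run at about 2-3 plants m-2.
#' @param irrigation_trigger Water-stress factor below which an automatic
#'   irrigation event fires, in \[0, 1\]; 0 disables auto-irrigation.
#' @param irrigation_depth mm applied per event.
#' @param soil_capacity Plant-available water capacity of the root zone, mm.
#' @param initial_soil_water Starting soil water, mm.
#' @param n_supply Season total plant-available N, kg ha-1.
#' @return An object of class \code{"management"}.
#' @export
management <- function(planting_date = as.Date("2023-04-25"), density = 2.5,
                       irrigation_trigger = 0.8, irrigation_depth = 25,
                       soil_capacity = 150, initial_soil_water = 120,
                       n_supply = 200) {
  if (density <= 0) stop("density must be positive")
  if (irrigation_trigger < 0 || irrigation_trigger > 1)
    stop("irrigation_trigger must be in [0, 1]")
  if (soil_capacity <= 0) stop("soil_capacity must be positive")
  structure(list(planting_date = as.Date(planting_date), density = density,
                 irrigation_trigger = irrigation_trigger,
                 irrigation_depth = irrigation_depth,
                 soil_capacity = soil_capacity,
                 initial_soil_water = min(initial_soil_water, soil_capacity),
                 n_supply = n_supply),
            class = "management")
}

#' Daily heat units
#'
#' Degree days from the daily mean of tmax and tmin above the base
#' temperature, capped at \code{tb - tg} (no extra development credit above
#' the optimum).
#'
#' @param tmax,tmin Daily temperature extremes, deg C.
#' @param tg Base temperature, deg C.
#' @param tb Optimal temperature, deg C (\code{tg < tb}).
#' @return Heat units, deg C day, in \[0, tb - tg\].
#' @examples
#' heat_units(30, 20, 10, 30)  # 15
#' heat_units(40, 34, 10, 30)  # capped at 20
#' @export
heat_units <- function(tmax, tmin, tg, tb) {
  stopifnot(tg < tb)
  pmin(pmax((tmax + tmin) / 2 - tg, 0), tb - tg)
}

#' Temperature stress factor
#'
#' Sine response rising from 0 at the base temperature to 1 at the optimum
#' and falling symmetrically back to 0 at \code{tb + (tb - tg)}:
#' \code{sin((pi/2) * (tavg - tg) / (tb - tg))} clamped to \[0, 1\] while the
#' scaled argument lies in \[0, 2\], and 0 outside.
#'
#' @param tavg Daily mean temperature, deg C.
#' @inheritParams heat_units
#' @return Stress factor in \[0, 1\] (1 = no stress).
#' @export
temperature_stress <- function(tavg, tg, tb) {
  stopifnot(tg < tb)
  r <- (tavg - tg) / (tb - tg)
  out <- ifelse(r >= 0 & r <= 2, sin(pi / 2 * r), 0)
  pmin(pmax(out, 0), 1)
}

#' Intercepted photosynthetically active radiation
#'
#' Beer's-law canopy interception: PAR is taken as half of global radiation
#' and the intercepted fraction is \code{1 - exp(-k_ext * lai)}.
#'
#' @param srad Global solar radiation, MJ m-2 day-1.
#' @param lai Leaf area index.
#' @param k_ext Canopy light-extinction coefficient.
#' @return Intercepted PAR, MJ m-2 day-1.
#' @export
intercepted_par <- function(srad, lai, k_ext = 0.65) {
  stopifnot(all(srad >= 0), all(lai >= 0))
  0.5 * srad * (1 - exp(-k_ext * lai))
}

#' Optimal nitrogen fraction of biomass
#'
#' Declining N dilution curve \code{a + b * exp(-c * hui)} anchored at the
#' three calibrated fractions: exact at emergence (hui = 0) and maturity
#' (hui = 1), and exact or least-squares at midseason (hui = 0.5) depending
#' on whether the three anchors admit an exact exponential fit.
#'
#' @param hui Heat-unit index (development stage), >= 0.
#' @param bn1,bn2,bn3 N fractions at emergence, midseason, maturity
#'   (\code{bn1 >= bn2 >= bn3 > 0}).
#' @return N fraction(s) of biomass; nonincreasing in \code{hui}.
#' @export
optimal_n_fraction <- function(hui, bn1, bn2, bn3) {
  stopifnot(all(hui >= 0))
  cf <- n_curve_coeffs(bn1, bn2, bn3)
  cf$a + cf$b * exp(-cf$c * hui)
}

n_curve_coeffs <- function(bn1, bn2, bn3) {
  if (!(bn1 >= bn2 && bn2 >= bn3 && bn3 > 0))
    stop("anchors must be nonincreasing: bn1 >= bn2 >= bn3 > 0")
  if (bn1 == bn3) return(list(a = bn3, b = 0, c = 1))
  u <- (bn2 - bn3) / (bn1 - bn2)  # = exp(-c/2) when exactly representable
  if (is.finite(u) && u > 0 && u < 1) {
    cc <- -2 * log(u)
    b <- (bn1 - bn2) / (1 - u)
    return(list(a = bn1 - b, b = b, c = cc))
  }
  # exact at the endpoints, least-squares at midseason
  obj <- function(cc) {
    b <- (bn1 - bn3) / (1 - exp(-cc))
    a <- bn1 - b
    (a + b * exp(-cc / 2) - bn2)^2
  }
  cc <- stats::optimize(obj, c(1e-6, 50))$minimum
  b <- (bn1 - bn3) / (1 - exp(-cc))
  list(a = bn1 - b, b = b, c = cc)
}

new_sim_state <- function(m) {
  list(day_index = 0L, cum_hu = 0, hui = 0, lai = 0, biomass = 0,
       plant_n = 0, n_taken = 0, soil_water = m$initial_soil_water,
       ts = 1, ws = 1, ns = 1, reg = 1,
       irrigation_applied = 0, n_stress_days = 0L, w_stress_days = 0L,
       lai_decline_base = NA_real_, pop_fac = NA_real_)
}

#' Advance the crop state by one day
#'
#' One daily timestep of the process model, in order: (1) heat-unit and
#' development-stage update; (2) temperature, water and nitrogen stress
#' factors, with the growth regulator REG taken as their minimum; (3) leaf
#' area growth along the calibrated S-curve (scaled by maximum LAI and the
#' plant-population factor) until the decline stage, then linear senescence;
#' (4) biomass gain as radiation use efficiency times Beer's-law intercepted
#' PAR times REG; (5) nitrogen uptake against the dilution-curve demand from
#' the fertigation pool; (6) soil-water bucket accounting with
#' Hargreaves-type evaporative demand and automatic irrigation.
#'
#' Primarily an internal workhorse of [run_season()], exported for
#' single-step inspection and testing.
#'
#' @param state State list from [run_season()]'s loop (or
#'   \code{pepsim:::new_sim_state}).
#' @param wx One-row data.frame with \code{tmax,tmin,srad,precip}.
#' @param p A [crop_params()] object.
#' @param m A [management()] object.
#' @return The updated state list.
#' @export
step_day <- function(state, wx, p, m) {
  if (is.data.frame(wx)) {
    if (nrow(wx) != 1L) stop("wx must be a single weather day")
    wx <- as.list(wx)
  }
  if (is.na(state$pop_fac))
    state$pop_fac <- population_factor(m$density, p$ppl_pts[[1]], p$ppl_pts[[2]])
  tavg <- (wx$tmax + wx$tmin) / 2

  # (1) phenology
  hu <- heat_units(wx$tmax, wx$tmin, p$tg, p$tb)
  hui_prev <- state$hui
  state$cum_hu <- state$cum_hu + hu
  state$hui <- min(state$cum_hu / p$phu, 1)

  # (2) stress factors; REG = min, never a product
  state$ts <- temperature_stress(tavg, p$tg, p$tb)
  pet <- max(0, 0.0135 * (tavg + 17.8) * wx$srad / 2.45)      # mm, Hargreaves
  demand <- pet * min(1, state$lai / 3)                        # transpiration
  state$ws <- min(1, state$soil_water / (0.5 * m$soil_capacity))
  opt_frac <- optimal_n_fraction(state$hui, p$bn1, p$bn2, p$bn3)
  state$ns <- if (state$biomass <= 0) 1 else
    min(1, state$plant_n / (opt_frac * state$biomass))
  state$reg <- min(state$ts, state$ws, state$ns)
  if (state$ws < 0.9) state$w_stress_days <- state$w_stress_days + 1L
  if (state$ns < 0.9) state$n_stress_days <- state$n_stress_days + 1L

  # (3) leaf area
  lai_max <- p$dmla * state$pop_fac
  if (state$hui <= p$dlai) {
    dlai_pot <- scurve_eval(state$hui, p$lai_curve) -
      scurve_eval(hui_prev, p$lai_curve)
    state$lai <- state$lai + lai_max * dlai_pot * state$reg
  } else {
    if (is.na(state$lai_decline_base)) state$lai_decline_base <- state$lai
    state$lai <- state$lai_decline_base * (1 - state$hui) / (1 - p$dlai)
  }

  # (4) biomass via RUE on intercepted PAR
  ipar <- intercepted_par(wx$srad, state$lai, p$k_ext)
  state$ipar <- ipar
  state$biomass <- state$biomass + p$wa * ipar * state$reg

  # (5) nitrogen uptake from the pro-rata fertigation pool
  avail_n <- m$n_supply * state$hui - state$n_taken
  n_demand <- max(0, opt_frac * state$biomass - state$plant_n)
  uptake <- min(n_demand, max(0, avail_n))
  state$plant_n <- state$plant_n + uptake
  state$n_taken <- state$n_taken + uptake

  # (6) soil-water bucket and auto-irrigation; evaporative demand is split
  # by canopy cover: transpiration from intercepted energy, soil evaporation
  # from the fraction passing through the canopy, both throttled as the
  # bucket empties
  state$soil_water <- min(m$soil_capacity, state$soil_water + wx$precip)
  es_pot <- pet * exp(-p$k_ext * state$lai)
  aet <- min(state$soil_water, (demand + es_pot) * state$ws)
  state$soil_water <- state$soil_water - aet
  if (m$irrigation_trigger > 0 && state$ws < m$irrigation_trigger) {
    state$soil_water <- min(m$soil_capacity, state$soil_water + m$irrigation_depth)
    state$irrigation_applied <- state$irrigation_applied + m$irrigation_depth
  }

  state$day_index <- state$day_index + 1L
  state
}

#' Simulate one growing season
#'
#' Runs the daily process model from planting until physiological maturity
#' (development stage reaching 1) or until the weather series is exhausted.
#' Yield is formed through a harvest index that ramps linearly from 0 at the
#' flowering stage to the calibrated value at maturity, which also lets
#' mid-season harvests be represented.
#'
#' @param p A [crop_params()] object.
#' @param wx A [weather_series()] covering the planting date onward.
#' @param m A [management()] object.
#' @return An object of class \code{"pepper_sim"}: list with the daily
#'   \code{trajectory} data.frame, \code{maturity_date}, \code{matured}
#'   flag, \code{final_biomass} and \code{yield} (dry Mg ha-1),
#'   \code{total_irrigation} (mm), stress-day tallies, and the inputs.
#' @examples
#' p <- get_parameter_set("PHR18", "control")
#' wx <- greenhouse_series(28, 18, n_days = 120)
#' run_season(p, wx, m = management(planting_date = wx$date[1]))
#' @export
run_season <- function(p, wx, m = management()) {
  stopifnot(inherits(p, "crop_params"), inherits(wx, "weather_series"),
            inherits(m, "management"))
  wxd <- as.data.frame(wx)
  wxd <- wxd[wxd$date >= m$planting_date, , drop = FALSE]
  if (nrow(wxd) == 0) stop("weather series does not cover the planting date")
  if (wxd$date[1] != m$planting_date)
    stop("weather series starts after the planting date")
  if (nrow(wxd) < 10) stop("weather series shorter than 10 days from planting")

  state <- new_sim_state(m)
  n <- nrow(wxd)
  cols <- c("hui", "lai", "biomass", "plant_n", "soil_water",
            "ts", "ws", "ns", "reg", "ipar", "irrigation")
  rec <- matrix(NA_real_, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  tmaxv <- wxd$tmax; tminv <- wxd$tmin; sradv <- wxd$srad; precv <- wxd$precip
  last <- 0L
  for (i in seq_len(n)) {
    state <- step_day(state, list(tmax = tmaxv[i], tmin = tminv[i],
                                  srad = sradv[i], precip = precv[i]), p, m)
    rec[i, ] <- c(state$hui, state$lai, state$biomass, state$plant_n,
                  state$soil_water, state$ts, state$ws, state$ns, state$reg,
                  state$ipar, state$irrigation_applied)
    last <- i
    if (state$hui >= 1) break
  }
  traj <- data.frame(date = wxd$date[seq_len(last)], day_index = seq_len(last),
                     rec[seq_len(last), , drop = FALSE])
  matured <- state$hui >= 1
  hi_real <- realized_hi(state$hui, p)
  final_biomass <- state$biomass / 1000            # kg -> Mg ha-1
  yield <- hi_real * final_biomass
  structure(list(
    trajectory = traj,
    maturity_date = traj$date[last],
    matured = matured,
    final_hui = state$hui,
    final_biomass = final_biomass,
    yield = yield,
    realized_hi = hi_real,
    total_irrigation = state$irrigation_applied,
    n_stress_days = state$n_stress_days,
    w_stress_days = state$w_stress_days,
    params = p, management = m,
    weather_site = attr(wx, "site"),
    weather_provenance = attr(wx, "provenance")),
    class = "pepper_sim")
}

realized_hi <- function(hui, p) {
  p$hi * min(1, max(0, (hui - p$hui_flower) / (1 - p$hui_flower)))
}

#' Maturity advance under a warming delta
#'
#' Days by which physiological maturity arrives earlier when the whole
#' weather series is warmed by \code{delta_t}; non-negative whenever mean
#' season temperatures stay at or below the optimum (capped degree days are
#' monotone in temperature).
#'
#' @inheritParams run_season
#' @param delta_t Warming increment, deg C.
#' @return Integer days (baseline maturity minus perturbed maturity). If the
#'   perturbed run fails to mature the shift to end-of-season is returned
#'   with attribute \code{matured = FALSE}.
#' @export
maturity_shift <- function(p, wx, m, delta_t) {
  base <- run_season(p, wx, m)
  if (!base$matured) stop("baseline run does not reach maturity")
  pert <- run_season(p, apply_delta(wx, delta_t), m)
  shift <- as.integer(base$maturity_date - pert$maturity_date)
  attr(shift, "matured") <- pert$matured
  shift
}

#' @export
print.pepper_sim <- function(x, ...) {
  cat(sprintf("<pepper_sim> %s / %s (%s), %d days from %s\n",
              x$params$accession, x$params$condition, x$params$setting,
              nrow(x$trajectory), x$trajectory$date[1]))
  cat(sprintf("  maturity: %s (%s, final stage %.2f)\n", x$maturity_date,
              if (x$matured) "reached" else "season end", x$final_hui))
  cat(sprintf("  biomass %.2f Mg ha-1 dry, yield %.2f Mg ha-1 dry (HI %.2f)\n",
              x$final_biomass, x$yield, x$realized_hi))
  cat(sprintf("  irrigation %.0f mm; stress days: water %d, nitrogen %d\n",
              x$total_irrigation, x$w_stress_days, x$n_stress_days))
  invisible(x)
}

#' @export
summary.pepper_sim <- function(object, ...) {
  tr <- object$trajectory
  out <- list(
    accession = object$params$accession, condition = object$params$condition,
    days = nrow(tr), matured = object$matured,
    maturity_date = object$maturity_date,
    peak_lai = max(tr$lai), final_biomass = object$final_biomass,
    yield = object$yield, realized_hi = object$realized_hi,
    mean_reg = mean(tr$reg), total_irrigation = object$total_irrigation,
    w_stress_days = object$w_stress_days, n_stress_days = object$n_stress_days)
  class(out) <- "summary.pepper_sim"
  out
}

#' @export
print.summary.pepper_sim <- function(x, ...) {
  cat(sprintf("Season summary: %s / %s\n", x$accession, x$condition))
  cat(sprintf("  %d days, matured: %s (%s)\n", x$days, x$matured, x$maturity_date))
  cat(sprintf("  peak LAI %.2f, mean growth regulator %.3f\n", x$peak_lai, x$mean_reg))
  cat(sprintf("  biomass %.2f, yield %.2f Mg ha-1 dry (HI %.2f)\n",
              x$final_biomass, x$yield, x$realized_hi))
  cat(sprintf("  irrigation %.0f mm; stress days water %d / nitrogen %d\n",
              x$total_irrigation, x$w_stress_days, x$n_stress_days))
  invisible(x)
}

#' @export
coef.pepper_sim <- function(object, ...) {
  p <- object$params
  c(wa = p$wa, hi = p$hi, tb = p$tb, tg = p$tg, dmla = p$dmla,
    phu = p$phu, dlai = p$dlai, k_ext = p$k_ext, hui_flower = p$hui_flower)
}

#' Plot a simulated season
#'
#' Two-panel base-graphics display: leaf area index and accumulated
#' above-ground biomass against development stage, with stress factors below.
#'
#' @param x A \code{pepper_sim} object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pepper_sim <- function(x, ...) {
  tr <- x$trajectory
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(old))
  graphics::plot(tr$date, tr$lai, type = "l", xlab = "date", ylab = "LAI",
                 main = sprintf("%s / %s", x$params$accession, x$params$condition), ...)
  graphics::par(new = TRUE)
  graphics::plot(tr$date, tr$biomass / 1000, type = "l", lty = 2, axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("biomass (Mg ha-1)", side = 4, line = 2.5)
  graphics::plot(tr$date, tr$reg, type = "l", ylim = c(0, 1), xlab = "date",
                 ylab = "stress factor")
  graphics::lines(tr$date, tr$ts, col = "red", lty = 3)
  graphics::lines(tr$date, tr$ws, col = "blue", lty = 3)
  graphics::lines(tr$date, tr$ns, col = "darkgreen", lty = 3)
  graphics::legend("bottomleft", c("REG", "temperature", "water", "nitrogen"),
                   col = c("black", "red", "blue", "darkgreen"),
                   lty = c(1, 3, 3, 3), cex = 0.7, bty = "n")
  invisible(x)
}
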