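#' Kjeldahl total nitrogen
#'
#' Total N (g per kg of dried sample) from an acid-digestion/distillation
#' titration: \code{((ml_sample - ml_blank) * normality * 14.01 * 100) /
#' (1000 * sample_mass)}, where 14.01 is the molar mass of nitrogen.
#'
#' @param ml_sample,ml_blank mL of HCl titrated for the sample and the
#'   blank; \code{ml_sample >= ml_blank} (a smaller sample volume signals a
#'   titration fault).
#' @param hcl_normality HCl normality, equivalents per litre (e.g. 0.1).
#' @param sample_mass Dried sample mass, g (> 0).
#' @return Total N, g per kg sample. Vectorized.
#' @examples
#' kjeldahl_total_n(10, 0, 0.1, 1)  # 14.01
#' @export
kjeldahl_total_n <- function(ml_sample, ml_blank, hcl_normality, sample_mass) {
  if (any(sample_mass <= 0)) stop("sample_mass must be positive")
  if (any(ml_sample < 0 | ml_blank < 0)) stop("titration volumes must be non-negative")
  if (any(ml_sample < ml_blank))
    stop("ml_sample below ml_blank: titration fault")
  ((ml_sample - ml_blank) * hcl_normality * 14.01 * 100) / (1000 * sample_mass)
}

#' Harvest index from a mass pair
#'
#' Economic yield over above-ground biomass, reported to 2 decimal places
#' (the precision at which harvest indices are conventionally tabulated).
#'
#' @param fruit_mass Fruit (yield) mass.
#' @param total_mass Total above-ground mass, same units, > 0 and
#'   \code{>= fruit_mass}.
#' @return Harvest index rounded to 2 decimals. Vectorized.
#' @examples
#' harvest_index(91, 326)  # 0.28
#' @export
harvest_index <- function(fruit_mass, total_mass) {
  if (any(total_mass <= 0)) stop("total_mass must be positive")
  if (any(fruit_mass < 0 | fruit_mass > total_mass))
    stop("need 0 <= fruit_mass <= total_mass")
  round(fruit_mass / total_mass, 2)
}

#' Fit the leaf-area development curve and re-encode it as point codes
#'
#' Normalizes measured LAI by the maximum (\code{dmla}), fits the S-curve
#' coefficients by least squares on the exact linearization
#' \code{log(x (1 - y) / y) = l1 - l2 x}, and re-encodes the fitted curve as
#' the two packed point codes used in parameter tables: the first at the
#' observed season fraction closest to 10\% of the season, the second at the
#' season fraction where the fitted curve reaches 95\% of maximum (the
#' plateau anchor). Noiseless observations generated from a pair of codes
#' with a 0.95 second ordinate reproduce those codes exactly.
#'
#' @param season_fraction Fractions of the growing season in (0, 1\],
#'   within the growth phase (at or before the leaf-area decline stage).
#' @param lai Measured leaf area index at those fractions; must not exceed
#'   \code{dmla}.
#' @param dmla Maximum leaf area index used for normalization.
#' @return List with \code{dlap1}, \code{dlap2} (packed codes) and the
#'   fitted \code{coeffs} ([solve_scurve()] object).
#' @export
fit_lai_curve <- function(season_fraction, lai, dmla) {
  stopifnot(length(season_fraction) == length(lai))
  if (any(lai > dmla + 1e-9)) stop("lai exceeds dmla")
  y <- lai / dmla
  usable <- season_fraction > 0 & y > 1e-3 & y < 1 - 1e-3
  x <- season_fraction[usable]; y <- y[usable]
  if (length(unique(x)) < 2)
    stop("need at least 2 usable points with distinct season fractions")
  # initialize from the exact linearization, restricted to mid-range points
  # where log(x (1 - y) / y) is well conditioned; refine by nonlinear least
  # squares on the original scale (robust to noise near the tails)
  mid <- y > 0.05 & y < 0.95
  if (sum(mid) < 2) mid <- rep(TRUE, length(y))
  z <- log(x[mid] * (1 - y[mid]) / y[mid])
  init <- stats::lm.fit(cbind(1, -x[mid]), z)$coefficients
  if (!all(is.finite(init))) stop("points imply a degenerate curve")
  sse <- function(par) {
    cf <- structure(list(l1 = par[1], l2 = par[2]), class = "scurve_coeffs")
    sum((scurve_eval(x, cf) - y)^2)
  }
  if (sse(unname(init)) > 1e-14) {
    opt <- stats::optim(unname(init), sse, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    init <- opt$par
  }
  l1 <- unname(init[1]); l2 <- unname(init[2])
  if (!is.finite(l2) || l2 <= 0) stop("points imply a non-increasing curve")
  cf <- structure(list(l1 = l1, l2 = l2), class = "scurve_coeffs")
  x1 <- x[which.min(abs(x - 0.10))]
  y1 <- scurve_eval(x1, cf)
  if (y1 <= 0.005 || y1 >= 0.995) stop("fitted curve degenerate near the first anchor")
  code1 <- round(100 * x1) + round(100 * y1) / 100
  # plateau anchor: season fraction where the fitted curve crosses 95% of
  # maximum, solved within the observed range only; if the curve has not
  # plateaued by the last observation, that last fraction is reported (no
  # extrapolation beyond the data)
  xmax <- max(x)
  if (scurve_eval(xmax, cf) < 0.95 - 1e-9) {
    x2 <- xmax
  } else {
    g <- function(xx) scurve_eval(xx, cf) - 0.95
    x2 <- stats::uniroot(g, c(1e-9, xmax), tol = 1e-10, extendInt = "upX")$root
  }
  code2 <- round(100 * x2) + 0.95
  list(dlap1 = code1, dlap2 = code2, coeffs = cf)
}

#' Midseason and maturity nitrogen fractions from stage measurements
#'
#' N mass fraction of biomass at the sampling stage closest to midseason
#' (development stage 0.5) and the one closest to maturity (stage 1.0),
#' reported to 3 significant figures.
#'
#' @param total_n Total plant N per stage (g per plant, or any mass unit
#'   consistent with \code{biomass_dry}).
#' @param biomass_dry Dry above-ground biomass per stage, same basis, > 0.
#' @param hui Development stage (heat-unit index) of each sampling, strictly
#'   increasing.
#' @return Named numeric \code{c(bn2 = , bn3 = )}.
#' @export
estimate_bn <- function(total_n, biomass_dry, hui) {
  stopifnot(length(total_n) == length(biomass_dry),
            length(total_n) == length(hui))
  if (length(hui) < 2) stop("need measurements at >= 2 stages")
  if (any(diff(hui) <= 0)) stop("stages out of order: hui must be increasing")
  if (any(biomass_dry <= 0)) stop("zero or negative biomass at a stage")
  if (any(total_n < 0)) stop("negative total N")
  frac <- total_n / biomass_dry
  i2 <- which.min(abs(hui - 0.5))
  i3 <- which.min(abs(hui - 1.0))
  c(bn2 = signif(frac[i2], 3), bn3 = signif(frac[i3], 3))
}

grid_search_1d <- function(values, loss_fn) {
  best <- NULL; best_loss <- Inf
  for (v in values) {
    l <- loss_fn(v)
    if (is.finite(l) && l < best_loss) { best <- v; best_loss <- l }
  }
  if (is.null(best)) stop("no candidate produced a finite yield error")
  best
}

#' Estimate a site's potential heat units from measured yield
#'
#' Grid search over PHU: each candidate re-runs the season simulation and
#' the candidate minimizing the absolute difference between simulated and
#' measured yield is returned. Ties break toward the smaller PHU (earlier
#' maturity).
#'
#' @inheritParams run_season
#' @param measured_yield Measured dry yield, Mg ha-1.
#' @param search Numeric \code{c(lo, hi, step)} bracketing the PHU grid;
#'   default (1200, 3500, 50) brackets the calibrated greenhouse values and
#'   typical Korean site requirements.
#' @param objective \code{"yield"} (absolute yield error, default) or
#'   \code{"maturity"} (absolute maturity-date error in days, against
#'   \code{measured_yield} interpreted as a target day-of-run).
#' @return The selected PHU, deg C day.
#' @export
estimate_phu <- function(p, wx, m, measured_yield,
                         search = c(1200, 3500, 50), objective = "yield") {
  lo <- search[1]; hi <- search[2]; step <- search[3]
  if (!(lo < hi) || step <= 0) stop("malformed search range: need lo < hi, step > 0")
  grid <- seq(lo, hi, by = step)
  loss <- function(phu) {
    pp <- p; pp$phu <- phu
    sim <- run_season(pp, wx, m)
    if (objective == "maturity")
      abs(nrow(sim$trajectory) - measured_yield)
    else abs(sim$yield - measured_yield)
  }
  grid_search_1d(grid, loss)
}

#' Estimate the open-field radiation use efficiency from measured yield
#'
#' Grid search over the potential growth rate WA with all other parameters
#' fixed, minimizing absolute yield error; ties break toward the smaller WA.
#' Used to carry a greenhouse-calibrated set into open-field conditions,
#' where realized radiation use efficiency is lower.
#'
#' @inheritParams estimate_phu
#' @param search Numeric \code{c(lo, hi, step)} for the WA grid.
#' @return The selected WA, kg ha-1 per MJ m-2.
#' @export
estimate_wa_field <- function(p, wx, m, measured_yield,
                              search = c(15, 40, 1)) {
  lo <- search[1]; hi <- search[2]; step <- search[3]
  if (!(lo < hi) || step <= 0) stop("malformed search range: need lo < hi, step > 0")
  grid <- seq(lo, hi, by = step)
  loss <- function(wa) {
    pp <- p; pp$wa <- wa
    abs(run_season(pp, wx, m)$yield - measured_yield)
  }
  grid_search_1d(grid, loss)
}

#' Per-plant fresh mass to areal dry yield
#'
#' Converts a per-plant fresh mass and moisture content to a dry areal
#' yield: \code{fresh * (1 - moisture/100) * density * 0.01} Mg ha-1
#' (100 g dry per m2 equals 1 Mg ha-1).
#'
#' @param fresh_mass Fresh mass, g per plant.
#' @param moisture Moisture content, percent of fresh mass, in \[0, 100\].
#' @param density Plants per square metre.
#' @return Dry yield, Mg ha-1. Vectorized.
#' @export
fresh_to_dry_areal <- function(fresh_mass, moisture, density) {
  if (any(moisture < 0 | moisture > 100)) stop("moisture must be in [0, 100]")
  if (any(fresh_mass < 0) || any(density < 0)) stop("masses and density must be non-negative")
  fresh_mass * (1 - moisture / 100) * density * 0.01
}
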