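#' Construct a crop parameter set
#'
#' The unit of calibration and simulation: every parameter the daily growth
#' engine consumes. Usually obtained from the packaged registry via
#' [get_parameter_set()]; this constructor validates user-supplied sets.
#'
#' @param accession Accession label, e.g. \code{"PHR18"}.
#' @param condition Growing condition the set was calibrated under:
#'   \code{"control"} or \code{"heat"}.
#' @param wa Potential growth rate (radiation use efficiency), kg ha-1 per
#'   MJ m-2 intercepted photosynthetically active radiation.
#' @param hi Harvest index: yield / above-ground biomass, in (0, 1].
#' @param tb Optimal temperature for growth, deg C.
#' @param tg Base (minimum) temperature for growth, deg C; must be < \code{tb}.
#' @param dmla Maximum leaf area index.
#' @param dlap1,dlap2 Packed point codes of the leaf-area development curve
#'   (percent x scale), see [decode_point_code()].
#' @param ppl1,ppl2 Packed point codes of the plant-population curve
#'   (absolute x scale, plants m-2).
#' @param cny Normal N fraction of yield.
#' @param bn1,bn2,bn3 Normal N fraction of biomass at emergence, midseason
#'   and maturity; must satisfy \code{bn1 >= bn2 >= bn3 > 0}.
#' @param phu Potential heat units from planting to physiological maturity,
#'   deg C day.
#' @param dlai Fraction of the growing season after which leaf area declines,
#'   in (0, 1].
#' @param k_ext Beer's-law canopy light-extinction coefficient.
#' @param hui_flower Heat-unit index at which harvest index starts accruing.
#' @param setting \code{"greenhouse"} or \code{"field"} (bookkeeping only).
#' @return An object of class \code{"crop_params"}.
#' @export
crop_params <- function(accession, condition, wa, hi, tb, tg, dmla,
                        dlap1, dlap2, ppl1, ppl2, cny, bn1, bn2, bn3, phu,
                        dlai = 0.99, k_ext = 0.65, hui_flower = 0.30,
                        setting = "greenhouse") {
  p <- list(accession = accession, condition = condition, setting = setting,
            wa = wa, hi = hi, tb = tb, tg = tg, dmla = dmla,
            dlap1 = dlap1, dlap2 = dlap2, ppl1 = ppl1, ppl2 = ppl2,
            cny = cny, bn1 = bn1, bn2 = bn2, bn3 = bn3, phu = phu,
            dlai = dlai, k_ext = k_ext, hui_flower = hui_flower)
  validate_crop_params(p)
  # decode curve points once; engine reuses them every day
  p$dlap_pts <- list(decode_point_code(dlap1, "percent"),
                     decode_point_code(dlap2, "percent"))
  p$ppl_pts <- list(decode_point_code(ppl1, "absolute"),
                    decode_point_code(ppl2, "absolute"))
  p$lai_curve <- solve_scurve(p$dlap_pts[[1]], p$dlap_pts[[2]])
  structure(p, class = "crop_params")
}

validate_crop_params <- function(p) {
  if (p$tg >= p$tb) stop("base temperature tg must be below optimal tb")
  if (p$hi <= 0 || p$hi > 1) stop("harvest index must be in (0, 1]")
  if (!(p$bn1 >= p$bn2 && p$bn2 >= p$bn3 && p$bn3 > 0))
    stop("nitrogen fractions must satisfy bn1 >= bn2 >= bn3 > 0")
  if (p$phu <= 0) stop("phu must be positive")
  if (p$dlai <= 0 || p$dlai > 1) stop("dlai must be in (0, 1]")
  if (p$wa <= 0 || p$dmla <= 0) stop("wa and dmla must be positive")
  d1 <- decode_point_code(p$dlap1, "percent")
  d2 <- decode_point_code(p$dlap2, "percent")
  if (!(d1[["x"]] < d2[["x"]] && d1[["y"]] < d2[["y"]]))
    stop("decoded leaf-area points must be strictly increasing in x and y")
  invisible(p)
}

param_registry <- function() {
  path <- system.file("extdata", "parameter_sets.yaml", package = "pepsim")
  yaml::read_yaml(path)
}

#' Retrieve a packaged crop parameter set
#'
#' Returns one of the four calibrated accession-by-condition parameter sets
#' (PHR18/PHR23 under control or heat stress). With
#' \code{setting = "field"} the greenhouse radiation use efficiency is
#' replaced by its open-field value (27 for the control sets, the same
#' 27/33 proportional reduction for the others) and the leaf-area decline
#' onset moves to 0.9 of the season, matching open-field practice of
#' harvesting as leaf area declines.
#'
#' @param accession \code{"PHR18"} or \code{"PHR23"}.
#' @param condition \code{"control"} or \code{"heat"}.
#' @param setting \code{"greenhouse"} (registry values verbatim) or
#'   \code{"field"}.
#' @return A [crop_params()] object.
#' @examples
#' get_parameter_set("PHR18", "control")
#' get_parameter_set("PHR18", "control", setting = "field")$wa  # 27
#' @export
get_parameter_set <- function(accession = c("PHR18", "PHR23"),
                              condition = c("control", "heat"),
                              setting = c("greenhouse", "field")) {
  reg <- param_registry()
  valid_acc <- setdiff(names(reg), "defaults")
  if (!is.character(accession) || !accession[1] %in% valid_acc)
    stop("unknown accession '", accession[1], "'; valid: ",
         paste(valid_acc, collapse = ", "))
  accession <- accession[1]
  valid_cond <- names(reg[[accession]])
  if (!is.character(condition) || !condition[1] %in% valid_cond)
    stop("unknown condition '", condition[1], "'; valid: ",
         paste(valid_cond, collapse = ", "))
  condition <- condition[1]
  setting <- match.arg(setting)
  v <- reg[[accession]][[condition]]
  d <- reg$defaults
  wa <- v$WA
  dlai <- d$DLAI
  if (setting == "field") {
    wa <- round(v$WA * d$WA_field_scale, 2)
    dlai <- d$DLAI_field
  }
  crop_params(accession = accession, condition = condition,
              wa = wa, hi = v$HI, tb = v$TB, tg = v$TG, dmla = v$DMLA,
              dlap1 = v$DLAP1, dlap2 = v$DLAP2, ppl1 = v$PPL1, ppl2 = v$PPL2,
              cny = v$CNY, bn1 = v$BN1, bn2 = v$BN2, bn3 = v$BN3, phu = v$PHU,
              dlai = dlai, k_ext = d$k_ext, hui_flower = d$hui_flower,
              setting = setting)
}

#' @export
print.crop_params <- function(x, ...) {
  cat(sprintf("<crop_params> %s / %s (%s)\n", x$accession, x$condition, x$setting))
  cat(sprintf("  WA=%g kg ha-1 per MJ m-2, HI=%g, PHU=%g C day\n", x$wa, x$hi, x$phu))
  cat(sprintf("  TB=%g C, TG=%g C, DMLA=%g, DLAI=%g\n", x$tb, x$tg, x$dmla, x$dlai))
  cat(sprintf("  LAI curve codes %g / %g, population codes %g / %g\n",
              x$dlap1, x$dlap2, x$ppl1, x$ppl2))
  cat(sprintf("  N fractions: CNY=%g, BN=%g/%g/%g\n", x$cny, x$bn1, x$bn2, x$bn3))
  invisible(x)
}
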