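read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pepsim")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged reference datasets
#'
#' Plain-text summary tables shipped with the package, from the studies the
#' default parameter sets were calibrated against:
#'
#' \itemize{
#'   \item \code{greenhouse_yield_summary()}: per-plant total and fruit
#'     fresh masses (mean and dispersion) and harvest index for PHR18 and
#'     PHR23 under control and heat-stress greenhouse regimes, at the two
#'     harvest days (35 and 75 days after treatment start).
#'   \item \code{greenhouse_yield_differences()}: the corresponding
#'     tabulated integer percent differences (heat vs control).
#'   \item \code{greenhouse_morphology_summary()}: fruit counts, moisture,
#'     leaf area index, height, stem thickness and total plant N summaries.
#'   \item \code{field_site_yields()}: measured vs simulated dry yields at
#'     the open-field calibration site and the nine potential-heat-unit test
#'     locations (2021-2024), with measured/simulated ratios;
#'     \code{phu_test == 1} marks the sixteen heat-unit-test pairs.
#'   \item \code{heat_scenario_yields()}: published multi-site warming
#'     scenario yields (reference and +3/+4/+5 deg C) with integer percent
#'     changes, per accession.
#' }
#'
#' @return A data.frame (see each description).
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
greenhouse_yield_summary <- function() read_extdata("greenhouse_yield_summary.csv")

#' @rdname reference_tables
#' @export
greenhouse_yield_differences <- function() read_extdata("greenhouse_yield_differences.csv")

#' @rdname reference_tables
#' @export
greenhouse_morphology_summary <- function() read_extdata("greenhouse_morphology_summary.csv")

#' @rdname reference_tables
#' @export
field_site_yields <- function() read_extdata("field_site_yields.csv")

#' @rdname reference_tables
#' @export
heat_scenario_yields <- function() read_extdata("heat_scenario_yields.csv")
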