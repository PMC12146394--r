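#' Round half away from zero
#'
#' Integer rounding where .5 always moves away from zero (so -31.5 becomes
#' -32), the convention used for reported integer percent changes; base R's
#' \code{round()} uses banker's rounding and would disagree on exact halves.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Integer percent difference of a treatment relative to control
#'
#' \code{100 * (treatment - control) / control}, rounded half away from
#' zero to an integer.
#'
#' @param control_value Reference value, > 0.
#' @param treatment_value Comparison value.
#' @return Integer percent change. Vectorized.
#' @examples
#' percent_difference(326, 178)  # -45
#' @export
percent_difference <- function(control_value, treatment_value) {
  if (any(control_value <= 0)) stop("control value must be positive")
  round_half_away(100 * (treatment_value - control_value) / control_value)
}

#' Measured-to-simulated yield ratio
#'
#' @param measured Measured value.
#' @param simulated Simulated value, > 0.
#' @return \code{measured / simulated} rounded to 2 decimals. Vectorized.
#' @export
yield_ratio <- function(measured, simulated) {
  if (any(simulated <= 0)) stop("simulated value must be positive")
  round(measured / simulated, 2)
}

#' Goodness-of-fit statistics for measured vs simulated pairs
#'
#' Root-mean-square error, percent bias
#' (\code{100 * sum(m - s) / sum(m)}; positive when the model
#' underestimates) and the squared Pearson correlation.
#'
#' @param measured,simulated Paired numeric vectors (at least 1 pair for
#'   RMSE/PBIAS, at least 2 with variance in both margins for R2).
#' @return An object of class \code{"fit_stats"}: list with \code{rmse},
#'   \code{pbias} (signed), \code{pbias_abs}, \code{r2} (NA with a flag
#'   when undefined) and \code{n}.
#' @examples
#' fit_stats(c(10, 9), c(9, 10))
#' @export
fit_stats <- function(measured, simulated) {
  if (length(measured) != length(simulated)) stop("pair lengths differ")
  n <- length(measured)
  if (n < 1) stop("need at least one pair")
  rmse <- sqrt(mean((measured - simulated)^2))
  pbias <- 100 * sum(measured - simulated) / sum(measured)
  r2 <- NA_real_; r2_defined <- FALSE
  if (n >= 2 && stats::sd(measured) > 0 && stats::sd(simulated) > 0) {
    r2 <- stats::cor(measured, simulated)^2
    r2_defined <- TRUE
  }
  structure(list(rmse = rmse, pbias = pbias, pbias_abs = abs(pbias),
                 r2 = r2, r2_defined = r2_defined, n = n),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("fit over %d pairs: RMSE %.2f, PBIAS %.1f%% (|%.1f|%%), R2 %s\n",
              x$n, x$rmse, x$pbias, x$pbias_abs,
              if (x$r2_defined) sprintf("%.2f", x$r2) else "undefined"))
  invisible(x)
}

format_scenario_cell <- function(reference, value) {
  sprintf("%.2f(%d)", value, as.integer(percent_difference(reference, value)))
}

#' Scenario yield table with percent-change cells
#'
#' Builds the standard warming-impact report: one row per site with the
#' reference yield and, for each temperature increment, a
#' \code{"yield(percent)"} cell such as \code{"4.88(-35)"}.
#'
#' @param baseline Named numeric vector: site -> reference yield (Mg ha-1).
#' @param scenarios Named list (one element per increment, e.g.
#'   \code{"+3"}) of named numeric vectors with the same site names.
#' @param site_info Optional data.frame with columns \code{site},
#'   \code{province}, \code{city} to prepend.
#' @return An object of class \code{"scenario_table"} (a data.frame): site,
#'   optional province/city, \code{reference}, one formatted-cell column and
#'   one numeric yield + percent column per scenario.
#' @export
scenario_table <- function(baseline, scenarios, site_info = NULL) {
  sites <- names(baseline)
  if (is.null(sites)) stop("baseline must be a named vector (site -> yield)")
  out <- data.frame(site = sites, reference = round(unname(baseline), 2),
                    stringsAsFactors = FALSE)
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    miss <- setdiff(sites, names(sc))
    if (length(miss)) stop("scenario '", nm, "' missing site(s): ",
                           paste(miss, collapse = ", "))
    sc <- sc[sites]
    out[[paste0("yield_", nm)]] <- round(unname(sc), 2)
    out[[paste0("pct_", nm)]] <- as.integer(percent_difference(baseline, sc))
    out[[paste0("cell_", nm)]] <- mapply(format_scenario_cell, baseline, sc,
                                         USE.NAMES = FALSE)
  }
  if (!is.null(site_info)) out <- merge(site_info, out, by = "site", sort = FALSE)
  class(out) <- c("scenario_table", "data.frame")
  out
}

#' @export
print.scenario_table <- function(x, ...) {
  cells <- grep("^cell_", names(x), value = TRUE)
  show <- x[, c(intersect(c("province", "city", "site"), names(x)),
                "reference", cells)]
  names(show) <- sub("^cell_", "", names(show))
  print.data.frame(format(show), row.names = FALSE)
  invisible(x)
}

#' Write a report table as CSV and fixed-width text
#'
#' @param tab A data.frame (e.g. a [scenario_table()]).
#' @param path Output CSV path; a sibling \code{.txt} fixed-width rendering
#'   is written alongside when \code{text = TRUE}.
#' @param header_lines Optional \code{#}-prefixed provenance lines.
#' @param text Also write the fixed-width text rendering.
#' @return Invisibly, the CSV path.
#' @export
write_report_csv <- function(tab, path, header_lines = NULL, text = FALSE) {
  con <- file(path, "w")
  if (!is.null(header_lines)) writeLines(header_lines, con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE, quote = FALSE)
  close(con)
  if (text) {
    txt <- utils::capture.output(print.data.frame(format(as.data.frame(tab)),
                                                  row.names = FALSE))
    writeLines(c(if (!is.null(header_lines)) header_lines, txt),
               sub("\\.csv$", ".txt", path))
  }
  invisible(path)
}
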