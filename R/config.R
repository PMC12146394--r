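#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys (typos fail loudly
#' rather than silently falling back to defaults), fills defaults, and
#' enforces that any stochastic stage has a seed.
#'
#' Recognized top-level keys: \code{params} (list with \code{accession},
#' \code{condition}, \code{setting}, or \code{path} to a YAML registry),
#' \code{weather} (list with \code{csv} or \code{generator} =
#' list(latitude_band, years)), \code{management} (arguments of
#' [management()]), \code{scenario} (arguments of [scenario_spec()]),
#' \code{seed}, \code{out}, \code{log_level}, \code{force}.
#'
#' @param path Path to a YAML file.
#' @return An object of class \code{"run_config"} (a named list with
#'   defaults filled).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- c("params", "weather", "management", "scenario", "seed",
               "out", "log_level", "force")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  defaults <- list(
    params = list(accession = "PHR18", condition = "control",
                  setting = "greenhouse"),
    weather = list(generator = list(latitude_band = "korea-central",
                                    years = 2023L)),
    management = list(), scenario = NULL,
    seed = NULL, out = NULL, log_level = "info", force = FALSE)
  cfg <- utils::modifyList(defaults, raw)
  sub_allowed <- list(
    params = c("accession", "condition", "setting", "path"),
    management = names(formals(management)),
    scenario = names(formals(scenario_spec)),
    weather = c("csv", "generator"))
  for (k in names(sub_allowed)) {
    bad <- setdiff(names(cfg[[k]]), sub_allowed[[k]])
    if (length(bad)) stop("unknown config key(s) under '", k, "': ",
                          paste(bad, collapse = ", "))
  }
  stochastic <- is.null(cfg$weather$csv) || !is.null(cfg$scenario)
  if (stochastic && is.null(cfg$seed))
    stop("config declares a stochastic stage (generated weather or ",
         "scenarios) but no seed")
  structure(cfg, class = "run_config")
}

#' Provenance header lines for output files
#'
#' Every CSV the package writes can carry a comment header recording the
#' package version, the seed, and an MD5 hash of the configuration used, so
#' outputs are traceable to their inputs.
#'
#' @param seed Integer seed used for the run (or NA).
#' @param config Any R object describing the run configuration (hashed
#'   after \code{deparse}).
#' @param timestamp Include a wall-clock line; off by default so that
#'   identical seed + config yields byte-identical output files.
#' @return Character vector of \code{#}-prefixed lines.
#' @export
provenance_header <- function(seed = NA, config = NULL, timestamp = FALSE) {
  ver <- as.character(utils::packageVersion("pepsim"))
  hash <- "none"
  if (!is.null(config)) {
    tf <- tempfile()
    writeLines(deparse(config), tf)
    hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  c(sprintf("# pepsim %s", ver),
    sprintf("# seed: %s", seed),
    sprintf("# config_md5: %s", hash),
    if (timestamp) sprintf("# written: %s",
                           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Guarded output writing
#'
#' Refuses to overwrite an existing file unless \code{force} is set.
#'
#' @param path Target path.
#' @param force Allow overwriting.
#' @return The path, invisibly; errors if the file exists and
#'   \code{force = FALSE}.
#' @export
check_overwrite <- function(path, force = FALSE) {
  if (file.exists(path) && !force)
    stop("output file exists (use force = TRUE to overwrite): ", path)
  invisible(path)
}
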