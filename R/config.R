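# tiny FNV-1a hash over a deparsed object, for provenance records
.fnv1a <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12)),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Scenario configuration
#'
#' Bundles every run-time choice of a projection: the input objects, the
#' simulated period, the calendar-trend scenario, the transition-mask
#' preset, reporting settings and the PSA block. All headline defaults
#' (2.7% dementia decline, 1000 PSA iterations, 2015 standardisation
#' reference, 2025 horizon) live here as configuration, never as constants
#' inside the computation layers.
#'
#' @param initial A [population_tensor()] for the base year.
#' @param schedule A [transition_schedule()].
#' @param entrants An [entry_cohorts()].
#' @param std A [standard_population()].
#' @param dist Optional [parameter_distribution()] for the PSA.
#' @param base_year First simulated year (default: the initial tensor's
#'   year).
#' @param horizon Last reported year (default 2025). Internally the run is
#'   extended one further cycle so period mortality can be observed at the
#'   horizon.
#' @param scenario Trend scenario name (`"baseline"`, `"constant"`,
#'   `"fast"`) or `"none"` to use the schedule as supplied.
#' @param cvd_mortality_annual_decline CVD mortality (and hence incidence)
#'   decline used when a named scenario is applied.
#' @param mask_preset Transition-mask preset (default `"progressive"`).
#' @param standard_year Reference year label of the standard population
#'   (default 2015).
#' @param report_years Years reported in summary tables (default 2015 and
#'   the horizon).
#' @param age_bands Named list of reporting age bands.
#' @param psa List with `n_iter`, `master_seed`, `ess` overrides for
#'   [run_psa()].
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(initial, schedule, entrants, std, dist = NULL,
                            base_year = initial$year, horizon = 2025L,
                            scenario = "none",
                            cvd_mortality_annual_decline = NULL,
                            mask_preset = "progressive",
                            standard_year = 2015L,
                            report_years = NULL,
                            age_bands = list("65+" = c(65, Inf),
                                             "65-84" = c(65, 84),
                                             "75+" = c(75, Inf),
                                             "85+" = c(85, Inf)),
                            psa = list(n_iter = 1000L, master_seed = 1L)) {
  base_year <- as.integer(base_year); horizon <- as.integer(horizon)
  if (base_year >= horizon) stop("base_year must precede horizon")
  cfg <- structure(list(
    initial = initial, schedule = schedule, entrants = entrants, std = std,
    dist = dist, base_year = base_year, horizon = horizon,
    run_horizon = horizon + 1L,
    scenario = scenario,
    cvd_mortality_annual_decline = cvd_mortality_annual_decline,
    mask_preset = mask_preset, standard_year = as.integer(standard_year),
    report_years = if (is.null(report_years)) {
      c(max(base_year, 2015L), horizon)
    } else as.integer(report_years),
    age_bands = age_bands, psa = psa
  ), class = "scenario_config")
  cfg$hash <- .fnv1a(cfg[c("base_year", "horizon", "scenario",
                           "mask_preset", "standard_year", "report_years")])
  cfg
}

#' Scenario schedule for a configuration
#'
#' Returns the configured schedule with the named trend scenario applied
#' (relative to the configuration's base year), or unchanged for scenario
#' `"none"`.
#'
#' @param config A [scenario_config()].
#' @return A [transition_schedule()].
#' @export
scenario_schedule <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (identical(config$scenario, "none")) return(config$schedule)
  if (is.null(config$cvd_mortality_annual_decline)) {
    stop("applying a named scenario requires cvd_mortality_annual_decline")
  }
  spec <- trend_preset(config$scenario,
                       cvd_mortality_annual_decline =
                         config$cvd_mortality_annual_decline,
                       base_year = config$base_year)
  apply_trends(config$schedule, spec)
}

#' Load a scenario configuration from a YAML file
#'
#' The file names the input bundle directory (relative paths are resolved
#' against the config file) and any of the [scenario_config()] settings:
#'
#' ```yaml
#' bundle: bundle_dir
#' horizon: 2025
#' scenario: baseline
#' cvd_mortality_annual_decline: 0.02
#' mask_preset: progressive
#' psa: {n_iter: 1000, master_seed: 1}
#' ```
#'
#' @param path Path to the YAML config file.
#' @return A [scenario_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$bundle)) stop("config must name a 'bundle' directory")
  bdir <- y$bundle
  if (!grepl("^(/|[A-Za-z]:)", bdir)) {
    bdir <- file.path(dirname(normalizePath(path)), bdir)
  }
  bundle <- read_bundle(bdir)
  args <- list(initial = bundle$initial, schedule = bundle$schedule,
               entrants = bundle$entrants, std = bundle$std,
               dist = bundle$dist)
  for (nm in c("base_year", "horizon", "scenario",
               "cvd_mortality_annual_decline", "mask_preset",
               "standard_year", "report_years", "psa")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(scenario_config, args)
}
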