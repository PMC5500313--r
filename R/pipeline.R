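# one structured log line per pipeline stage
.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf("%s=%s", names(list(...)),
                                vapply(list(...), format, "")),
                        collapse = " ")))
}

#' Write a synthetic input bundle to a directory
#'
#' Emits the five inputs as plain-text files plus a provenance record:
#' `transition_schedule.csv.gz`, `initial_population.csv`,
#' `entry_cohorts.csv`, `standard_population.csv`, `dispersion.yaml` (the
#' PSA distribution family and effective sample size) and
#' `provenance.yaml` (the generating spec).
#'
#' @param bundle An `input_bundle` from [generate_inputs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "input_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_schedule(bundle$schedule, file.path(dir, "transition_schedule.csv.gz"))

  tn <- bundle$initial
  grid <- expand.grid(state = state_codes(), sex = tn$sexes, age = tn$ages,
                      stringsAsFactors = FALSE)
  df <- data.frame(age = grid$age, sex = grid$sex, state = grid$state,
                   count = sprintf("%.*g", .SCHEDULE_SIGDIGITS,
                                   as.vector(aperm(tn$counts, c(3, 2, 1)))))
  con <- file(file.path(dir, "initial_population.csv"), "wt")
  writeLines(c(paste0("# year: ", tn$year), "age,sex,state,count",
               paste(df$age, df$sex, df$state, df$count, sep = ",")), con)
  close(con)

  ec <- bundle$entrants
  utils::write.csv(data.frame(year = rep(rownames(ec), ncol(ec)),
                              sex = rep(colnames(ec), each = nrow(ec)),
                              entrants = as.vector(ec)),
                   file.path(dir, "entry_cohorts.csv"), row.names = FALSE,
                   quote = FALSE)

  sp <- bundle$std
  utils::write.csv(data.frame(age = rep(rownames(sp), ncol(sp)),
                              sex = rep(colnames(sp), each = nrow(sp)),
                              weight = sprintf("%.*g", .SCHEDULE_SIGDIGITS,
                                               as.vector(sp))),
                   file.path(dir, "standard_population.csv"),
                   row.names = FALSE, quote = FALSE)

  yaml::write_yaml(list(family = "dirichlet", ess = bundle$dist$ess),
                   file.path(dir, "dispersion.yaml"))
  spec <- bundle$spec
  yaml::write_yaml(list(generator = "synthetic_spec",
                        spec = rapply(unclass(spec), as.vector, how = "list"),
                        spec_hash = .fnv1a(unclass(spec))),
                   file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Read an input bundle directory
#'
#' @param dir Directory written by [write_bundle()] (or assembled by hand
#'   in the same layout).
#' @return A list of class `"input_bundle"`.
#' @export
read_bundle <- function(dir) {
  need <- c("transition_schedule.csv.gz", "initial_population.csv",
            "entry_cohorts.csv", "standard_population.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop("bundle directory ", dir, " is missing: ",
         paste(missing, collapse = ", "))
  }
  schedule <- read_schedule(file.path(dir, "transition_schedule.csv.gz"))

  ip_path <- file.path(dir, "initial_population.csv")
  first <- readLines(ip_path, n = 1L)
  base_year <- as.integer(sub("# year: *", "", first))
  ip <- utils::read.csv(ip_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  ages <- sort(unique(ip$age))
  sexes <- intersect(c("male", "female"), unique(ip$sex))
  counts <- array(0, c(length(ages), length(sexes), 10L))
  counts[cbind(match(ip$age, ages), match(ip$sex, sexes),
               match(ip$state, state_codes()))] <- ip$count
  initial <- population_tensor(counts, base_year, ages, sexes)

  ec <- utils::read.csv(file.path(dir, "entry_cohorts.csv"),
                        stringsAsFactors = FALSE)
  years <- sort(unique(ec$year))
  em <- matrix(0, length(years), length(sexes))
  em[cbind(match(ec$year, years), match(ec$sex, sexes))] <- ec$entrants
  entrants <- entry_cohorts(years, em, sexes)

  sp <- utils::read.csv(file.path(dir, "standard_population.csv"),
                        stringsAsFactors = FALSE)
  sages <- sort(unique(sp$age))
  sm <- matrix(0, length(sages), length(sexes))
  sm[cbind(match(sp$age, sages), match(sp$sex, sexes))] <- sp$weight
  std <- standard_population(sm, sages, sexes)

  dist <- NULL
  dpath <- file.path(dir, "dispersion.yaml")
  if (file.exists(dpath)) {
    dy <- yaml::read_yaml(dpath)
    if (identical(dy$family, "dirichlet")) {
      dist <- parameter_distribution(schedule, dy$ess)
    }
  }
  structure(list(schedule = schedule, initial = initial,
                 entrants = entrants, std = std, dist = dist, spec = NULL),
            class = "input_bundle")
}

#' Generate a synthetic input bundle (command entry point)
#'
#' Thin wrapper over [generate_inputs()] + [write_bundle()]: accepts a
#' [synthetic_spec()] or the path of a YAML file whose keys override the
#' spec's defaults.
#'
#' @param spec A [synthetic_spec()], a YAML file path, or NULL for the
#'   default spec.
#' @param out_dir Output directory.
#' @return The bundle directory, invisibly.
#' @export
cmd_generate <- function(spec = NULL, out_dir) {
  if (is.null(spec)) {
    spec <- synthetic_spec()
  } else if (is.character(spec)) {
    y <- yaml::read_yaml(spec)
    spec <- do.call(synthetic_spec, y)
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  .log_stage("generate", seed = spec$seed,
             ages = paste0(spec$age_min, "-", spec$age_max))
  bundle <- generate_inputs(spec)
  rep_ <- validate_schedule(bundle$schedule, transition_mask("progressive"))
  if (nrow(rep_) > 0L) {
    stop("generated schedule failed validation: ",
         paste(unique(rep_$issue), collapse = ", "))
  }
  write_bundle(bundle, out_dir)
  .log_stage("generate-done", dir = out_dir)
  invisible(out_dir)
}

#' Run a projection and write the summary tables (command entry point)
#'
#' Validates the (scenario-adjusted) schedule against the configured mask,
#' runs the projection from the base year to one cycle past the horizon,
#' and writes `trajectory.csv.gz`, `disability_counts.csv`,
#' `disability_types.csv`, `prevalence.csv` and `health_expectancy.csv`
#' into `out_dir`.
#'
#' @param config A [scenario_config()] or the path of a YAML config file.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the trajectory and the four tables.
#' @export
cmd_project <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .log_stage("project", scenario = config$scenario, hash = config$hash,
             horizon = config$horizon)

  schedule <- scenario_schedule(config)
  rep_ <- validate_schedule(schedule, default_mask(config))
  if (nrow(rep_) > 0L) {
    stop("schedule fails validation under mask preset '",
         config$mask_preset, "': ",
         paste(unique(rep_$issue), collapse = ", "))
  }
  traj <- run_projection(config$initial, schedule, config$entrants,
                         config$run_horizon,
                         provenance = list(config_hash = config$hash,
                                           scenario = config$scenario))
  report_years <- config$report_years
  count_bands <- config$age_bands[
    names(config$age_bands) %in% c("65+", "65-84", "85+")]
  counts <- disability_count_table(traj, report_years, bands = count_bands)
  types <- disability_count_table(
    traj, report_years, bands = count_bands, sexes = "all",
    dtypes = setdiff(disability_types(), "NONE"))
  prev_bands <- config$age_bands[
    names(config$age_bands) %in% c("65+", "75+", "85+")]
  prev <- prevalence_table(traj, config$std, report_years,
                           bands = prev_bands)
  he <- health_expectancy_table(traj, report_years)

  write_trajectory(traj, file.path(out_dir, "trajectory.csv.gz"))
  utils::write.csv(counts, file.path(out_dir, "disability_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(types, file.path(out_dir, "disability_types.csv"),
                   row.names = FALSE)
  utils::write.csv(prev, file.path(out_dir, "prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(he, file.path(out_dir, "health_expectancy.csv"),
                   row.names = FALSE)
  .log_stage("project-done", out = out_dir)
  invisible(list(trajectory = traj, counts = counts, types = types,
                 prevalence = prev, health_expectancy = he))
}

#' Run the probabilistic sensitivity analysis (command entry point)
#'
#' @param config A [scenario_config()] (with a `dist` element or a
#'   schedule to wrap) or a YAML config path.
#' @param out_dir Output directory for `psa.csv`.
#' @return Invisibly, the [run_psa()] result.
#' @export
cmd_psa <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  psa_block <- config$psa
  dist <- config$dist
  if (is.null(dist)) {
    ess <- if (!is.null(psa_block$ess)) psa_block$ess else 1000
    dist <- parameter_distribution(scenario_schedule(config), ess)
  } else if (!is.null(psa_block$ess)) {
    dist <- parameter_distribution(dist$central, psa_block$ess)
  }
  n_iter <- if (!is.null(psa_block$n_iter)) psa_block$n_iter else 1000L
  seed <- if (!is.null(psa_block$master_seed)) psa_block$master_seed else 1L
  .log_stage("psa", n_iter = n_iter, master_seed = seed)
  res <- run_psa(dist, config, n_iter = n_iter, master_seed = seed)
  out <- as.data.frame(res)
  out$n_iter <- attr(res, "n_iter")
  out$master_seed <- attr(res, "master_seed")
  utils::write.csv(out, file.path(out_dir, "psa.csv"), row.names = FALSE)
  .log_stage("psa-done", out = out_dir)
  invisible(res)
}

#' Validate a schedule file or configuration (command entry point)
#'
#' @param x A [transition_schedule()], schedule file path, or
#'   [scenario_config()].
#' @param mask_preset Mask preset to check against.
#' @return A [validate_schedule()] report.
#' @export
cmd_validate <- function(x, mask_preset = "progressive") {
  schedule <- if (inherits(x, "transition_schedule")) x
  else if (inherits(x, "scenario_config")) x$schedule
  else read_schedule(x)
  validate_schedule(schedule, transition_mask(mask_preset))
}
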