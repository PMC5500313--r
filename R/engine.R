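#' Population tensor
#'
#' Person counts indexed by (age, sex, state) for one calendar year. Counts
#' are real-valued: the engine is an expected-value cohort model, not a
#' microsimulation. Death-state counts are cumulative and are kept at the
#' age the person had at the start of the cycle in which they died, so every
#' (age, death-state) cell is monotone non-decreasing along a trajectory.
#'
#' @param counts Numeric array `[age, sex, state]`, all entries >= 0.
#' @param year Calendar year label.
#' @param ages Contiguous integer age vector.
#' @param sexes Character vector of sexes.
#' @return An object of class `"population_tensor"`.
#' @export
population_tensor <- function(counts, year, ages,
                              sexes = c("male", "female")) {
  ages <- as.integer(ages)
  expected <- c(length(ages), length(sexes), 10L)
  if (!is.numeric(counts) || length(dim(counts)) != 3L ||
      !all(dim(counts) == expected)) {
    stop("counts must be a numeric array of dim [",
         paste(expected, collapse = " x "), "]")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("population counts must be non-negative and non-missing")
  }
  dimnames(counts) <- list(age = as.character(ages), sex = sexes,
                           state = state_codes())
  structure(list(counts = counts, year = as.integer(year), ages = ages,
                 sexes = sexes),
            class = "population_tensor")
}

#' @export
print.population_tensor <- function(x, ...) {
  alive <- sum(x$counts[, , 1:8])
  dead <- sum(x$counts[, , 9:10])
  cat("<population_tensor> year", x$year,
      sprintf("- alive %.0f, cumulative deaths %.0f\n", alive, dead))
  invisible(x)
}

#' Entry-cohort series
#'
#' The exogenous stream of people entering the model disease-free at the
#' youngest age each year.
#'
#' @param years Integer calendar years.
#' @param entrants Numeric matrix `[year, sex]` (or vector recycled over
#'   sexes) of non-negative person counts.
#' @param sexes Character vector of sexes.
#' @return Matrix of class `"entry_cohorts"` with year rownames.
#' @export
entry_cohorts <- function(years, entrants, sexes = c("male", "female")) {
  years <- as.integer(years)
  if (!is.matrix(entrants)) {
    entrants <- matrix(entrants, nrow = length(years), ncol = length(sexes))
  }
  if (nrow(entrants) != length(years) || ncol(entrants) != length(sexes)) {
    stop("entrants must be a [year x sex] matrix")
  }
  if (anyNA(entrants) || any(entrants < 0)) {
    stop("entrant counts must be non-negative")
  }
  dimnames(entrants) <- list(year = as.character(years), sex = sexes)
  structure(entrants, class = c("entry_cohorts", "matrix", "array"))
}

# internal: look up the year's matrix block, [age, sex, from, to]
.schedule_slice <- function(schedule, year) {
  yi <- match(year, schedule$years)
  if (is.na(yi)) {
    stop("schedule has no matrices for year ", year,
         " (covers ", min(schedule$years), "-", max(schedule$years), ")")
  }
  block <- schedule$p[, , yi, , , drop = FALSE]
  dim(block) <- dim(schedule$p)[c(1L, 2L, 4L, 5L)]
  block
}

#' Advance the population by one annual cycle
#'
#' One engine step: (1) each (age, sex) occupancy vector is multiplied by
#' its transition matrix for the tensor's year; (2) survivors age by one
#' year, with survivors at the age cap pooled back into the cap age;
#' (3) the incoming year's entry cohort is added to the disease-free state
#' at the youngest age. New deaths are recorded at the age the person had
#' at the start of the cycle. Total persons are conserved: alive plus
#' cumulative deaths grow exactly by the entrants added (checked to 1e-6
#' relative tolerance).
#'
#' @param pop A [population_tensor()] for year t.
#' @param schedule A [transition_schedule()] covering year t.
#' @param entrants An [entry_cohorts()] covering year t + 1, or a single
#'   number per sex, or NULL for no entrants.
#' @return A [population_tensor()] for year t + 1.
#' @export
step_year <- function(pop, schedule, entrants = NULL) {
  stopifnot(inherits(pop, "population_tensor"),
            inherits(schedule, "transition_schedule"))
  if (!identical(pop$ages, schedule$ages)) {
    stop("population and schedule age ranges differ")
  }
  block <- .schedule_slice(schedule, pop$year)
  na <- length(pop$ages); ns <- length(pop$sexes)
  year_in <- pop$year + 1L

  ent <- rep(0, ns)
  if (!is.null(entrants)) {
    if (inherits(entrants, "entry_cohorts")) {
      yi <- match(as.character(year_in), rownames(entrants))
      if (is.na(yi)) {
        stop("entry-cohort series has no entry for year ", year_in)
      }
      ent <- entrants[yi, ]
    } else {
      ent <- rep_len(as.numeric(entrants), ns)
    }
    if (anyNA(ent) || any(ent < 0)) stop("entrant counts must be non-negative")
  }

  out <- array(0, dim(pop$counts))
  for (s in seq_len(ns)) {
    C <- matrix(pop$counts[, s, ], na, 10L)   # [age, state]
    P <- block[, s, , , drop = FALSE]         # [age, from, to]
    dim(P) <- c(na, 10L, 10L)
    newC <- matrix(0, na, 10L)
    for (j in 1:10) newC[, j] <- rowSums(C * P[, , j])
    aged <- matrix(0, na, 10L)
    aged[, 9:10] <- newC[, 9:10]               # deaths keep age at death
    if (na > 1L) {
      aged[2:na, 1:8] <- newC[1:(na - 1L), 1:8]  # survivors age one year
    }
    aged[na, 1:8] <- aged[na, 1:8] + newC[na, 1:8]  # pooling at the cap
    aged[1L, 1L] <- aged[1L, 1L] + ent[s]           # entrants into FREE
    out[, s, ] <- aged
  }

  res <- population_tensor(out, year_in, pop$ages, pop$sexes)
  total_in <- sum(pop$counts) + sum(ent)
  total_out <- sum(res$counts)
  if (abs(total_out - total_in) > 1e-6 * max(total_in, 1)) {
    stop(sprintf(
      "population not conserved stepping %d -> %d: in %.9g, out %.9g",
      pop$year, year_in, total_in, total_out))
  }
  res
}

#' Run the annual-cycle projection
#'
#' Applies [step_year()] repeatedly from the initial year to the horizon.
#' Deterministic given its inputs; population conservation is enforced at
#' every step.
#'
#' @param initial A [population_tensor()] for the base year.
#' @param schedule A [transition_schedule()] covering every simulated year
#'   (steps beyond the schedule's last year reuse its final-year matrices,
#'   mirroring the open-ended treatment of the age cap).
#' @param entrants An [entry_cohorts()] covering the simulated years, or
#'   NULL.
#' @param horizon Final calendar year.
#' @param provenance Optional list recorded on the trajectory.
#' @return An object of class `"trajectory"`: list with `years` and
#'   `tensors` (one [population_tensor()] per year), plus provenance.
#' @export
run_projection <- function(initial, schedule, entrants = NULL, horizon,
                           provenance = NULL) {
  stopifnot(inherits(initial, "population_tensor"))
  horizon <- as.integer(horizon)
  if (horizon < initial$year) stop("horizon precedes the initial year")
  years <- initial$year:horizon
  # allow stepping past the schedule's last year by reusing its final slice
  if (horizon > max(schedule$years) + 1L) {
    stop("schedule does not cover the projection years ",
         max(schedule$years) + 1L, "-", horizon - 1L)
  }
  tensors <- vector("list", length(years))
  tensors[[1L]] <- initial
  cur <- initial
  for (k in seq_along(years)[-1L]) {
    use_year <- min(cur$year, max(schedule$years))
    if (use_year != cur$year) {
      cur <- population_tensor(cur$counts, use_year, cur$ages, cur$sexes)
    }
    nxt <- step_year(cur, schedule, entrants)
    nxt$year <- years[k]
    tensors[[k]] <- nxt
    cur <- nxt
  }
  structure(list(years = years, tensors = tensors,
                 provenance = provenance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$years), "years:",
      min(x$years), "-", max(x$years), "\n")
  first <- x$tensors[[1L]]; last <- x$tensors[[length(x$tensors)]]
  cat(sprintf("  alive %s: %.0f   alive %s: %.0f\n",
              min(x$years), sum(first$counts[, , 1:8]),
              max(x$years), sum(last$counts[, , 1:8])))
  invisible(x)
}

#' Extract one year's tensor from a trajectory
#'
#' @param traj A trajectory from [run_projection()].
#' @param year Calendar year.
#' @return A [population_tensor()].
#' @export
trajectory_year <- function(traj, year) {
  stopifnot(inherits(traj, "trajectory"))
  k <- match(as.integer(year), traj$years)
  if (is.na(k)) {
    stop("trajectory does not cover year ", year,
         " (covers ", min(traj$years), "-", max(traj$years), ")")
  }
  traj$tensors[[k]]
}

#' Expected years spent in a set of states (absorbing-chain oracle)
#'
#' Expected number of years an individual entering the disease-free state
#' at `start_age` spends in `state_subset` before absorption, under the
#' fixed-year matrices of `schedule`. Computed by exhaustive forward
#' recursion over ages up to the cap, plus a closed-form geometric tail at
#' the cap age via the fundamental matrix of the alive-state block.
#'
#' Years are counted at the start of each completed interval: occupancy is
#' accumulated after each annual transition, so immediate certain death
#' yields 0 years and a constant survival probability s yields
#' `sum(s^k, k >= 1) = s / (1 - s)` in the uncapped limit.
#'
#' @param state_subset Character vector of alive state codes.
#' @param start_age Starting age.
#' @param sex `"male"` or `"female"`.
#' @param schedule A [transition_schedule()].
#' @param year Calendar year whose matrices are used at every age
#'   (period/fixed-year mode); defaults to the schedule's first year.
#' @return Expected years (numeric scalar).
#' @export
expected_sojourn <- function(state_subset, start_age, sex, schedule,
                             year = schedule$years[1L]) {
  stopifnot(inherits(schedule, "transition_schedule"))
  sub_idx <- .state_index(state_subset)
  if (any(sub_idx > 8L)) stop("state_subset must contain alive states only")
  si <- match(sex, schedule$sexes)
  if (is.na(si)) stop("unknown sex: ", sex)
  block <- .schedule_slice(schedule, year)
  ages <- schedule$ages
  a0 <- match(as.integer(start_age), ages)
  if (is.na(a0)) stop("start_age outside the schedule's age range")
  # death rows must be absorbing
  for (d in 9:10) {
    for (a in seq_along(ages)) {
      row <- block[a, si, d, ]
      if (abs(row[d] - 1) > 1e-9 || sum(abs(row[-d])) > 1e-9) {
        stop("death rows are not absorbing at age ", ages[a])
      }
    }
  }
  occ <- rep(0, 10L); occ[1L] <- 1  # start disease-free
  total <- 0
  na <- length(ages)
  if (a0 < na) {
    for (a in a0:(na - 1L)) {
      P <- block[a, si, , ]
      occ <- as.vector(occ %*% P)
      total <- total + sum(occ[sub_idx])
    }
  }
  # geometric tail at the age cap
  Pcap <- block[na, si, , ]
  Q <- Pcap[1:8, 1:8]
  IQ <- diag(8L) - Q
  if (abs(det(IQ)) < 1e-12) {
    stop("no mortality at the age cap: expected sojourn diverges")
  }
  # sum_{k>=1} occ_alive Q^k = occ_alive Q (I - Q)^{-1}
  tail_occ <- as.vector((occ[1:8] %*% Q) %*% solve(IQ))
  total + sum(tail_occ[sub_idx])
}

#' Export a trajectory as a delimited long table
#'
#' Columns (year, age, sex, state, count); provenance is written as
#' comment lines prefixed with `#`.
#'
#' @param traj A trajectory.
#' @param path Output path (`.gz` accepted).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- .open_write(path)
  on.exit(close(con))
  prov <- traj$provenance
  if (!is.null(prov)) {
    for (nm in names(prov)) {
      writeLines(sprintf("# %s: %s", nm, format(prov[[nm]])), con)
    }
  }
  writeLines("year,age,sex,state,count", con)
  for (k in seq_along(traj$years)) {
    tn <- traj$tensors[[k]]
    grid <- expand.grid(state = state_codes(), sex = tn$sexes,
                        age = tn$ages, stringsAsFactors = FALSE)
    cnt <- as.vector(aperm(tn$counts, c(3L, 2L, 1L)))
    writeLines(paste(tn$year, grid$age, grid$sex, grid$state,
                     sprintf("%.*g", .SCHEDULE_SIGDIGITS, cnt), sep = ","),
               con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @return A trajectory object (provenance comment lines are ignored).
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  years <- sort(unique(df$year))
  ages <- sort(unique(df$age))
  sexes <- intersect(c("male", "female"), unique(df$sex))
  tensors <- vector("list", length(years))
  for (k in seq_along(years)) {
    d <- df[df$year == years[k], ]
    counts <- array(0, c(length(ages), length(sexes), 10L))
    counts[cbind(match(d$age, ages), match(d$sex, sexes),
                 match(d$state, state_codes()))] <- d$count
    tensors[[k]] <- population_tensor(counts, years[k], ages, sexes)
  }
  structure(list(years = as.integer(years), tensors = tensors,
                 provenance = NULL), class = "trajectory")
}
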