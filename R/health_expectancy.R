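#' Period death probabilities from a trajectory
#'
#' Recovers the age-specific probability of dying q_a for one calendar year
#' from the trajectory itself: new deaths during the cycle (the increment in
#' the cumulative death-state counts, which the engine books at the age the
#' person had at the start of the cycle) divided by the alive population of
#' that age at the start.
#'
#' @param traj A trajectory covering `year` and `year + 1`.
#' @param year Calendar year.
#' @param sex `"all"`, `"male"` or `"female"`.
#' @return Named numeric vector `q_a` over the trajectory's ages.
#' @export
mortality_from_trajectory <- function(traj, year, sex = "all") {
  t0 <- trajectory_year(traj, year)
  t1 <- trajectory_year(traj, year + 1L)
  ssel <- .sex_sel(t0$sexes, sex)
  na <- length(t0$ages)
  alive0 <- rowSums(matrix(t0$counts[, ssel, 1:8], nrow = na))
  dead0 <- rowSums(matrix(t0$counts[, ssel, 9:10], nrow = na))
  dead1 <- rowSums(matrix(t1$counts[, ssel, 9:10], nrow = na))
  new_deaths <- dead1 - dead0
  if (any(new_deaths < -1e-6 * pmax(dead0, 1))) {
    stop("cumulative death counts decreased between ", year, " and ",
         year + 1L, "; trajectory is inconsistent")
  }
  new_deaths <- pmax(new_deaths, 0)
  if (any(alive0 == 0 & new_deaths > 0)) {
    stop("deaths recorded at age(s) with zero alive population: ",
         paste(t0$ages[alive0 == 0 & new_deaths > 0], collapse = ", "))
  }
  q <- ifelse(alive0 > 0, new_deaths / alive0, 0)
  q <- pmin(pmax(q, 0), 1)
  names(q) <- t0$ages
  q
}

#' Proportion disabled among the alive, by age
#'
#' The cross-sectional disability prevalence schedule pi_a feeding the
#' Sullivan decomposition.
#'
#' @inheritParams mortality_from_trajectory
#' @return Named numeric vector `pi_a` in \[0, 1\] over the trajectory's
#'   ages (0 where no one is alive).
#' @export
prevalence_from_trajectory <- function(traj, year, sex = "all") {
  tn <- trajectory_year(traj, year)
  ssel <- .sex_sel(tn$sexes, sex)
  na <- length(tn$ages)
  alive <- rowSums(matrix(tn$counts[, ssel, 1:8], nrow = na))
  dis <- rowSums(matrix(tn$counts[, ssel, .dtype_states("all")], nrow = na))
  pi_a <- ifelse(alive > 0, dis / alive, 0)
  names(pi_a) <- tn$ages
  pi_a
}

#' Build a period life table from age-specific death probabilities
#'
#' Standard columns from a radix of 100 000: survivors l_a, deaths d_a,
#' person-years L_a with a uniform within-interval death convention
#' (a_x = 0.5 at every age — there is no infant-mortality correction to make
#' from age 35), cumulative person-years T_a and remaining life expectancy
#' e_a = T_a / l_a.
#'
#' The oldest age is open-ended: its person-years are `l / m` where the
#' terminal central death rate m is derived from the terminal q by
#' `m = -log(1 - q)` (so q = 1 gives a closed interval with zero tail). A
#' terminal q of 0 leaves the table unbounded and is rejected.
#'
#' @param q Named numeric vector of death probabilities by age (contiguous
#'   ages; names taken as ages, else `ages` must be given).
#' @param ages Optional integer ages.
#' @param radix Survivors at the starting age (default 100 000).
#' @return A data frame of class `"life_table"` with columns `age`, `qx`,
#'   `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @export
build_life_table <- function(q, ages = NULL, radix = 1e5) {
  if (is.null(ages)) {
    if (is.null(names(q))) stop("supply ages or a named q vector")
    ages <- as.integer(names(q))
  }
  n <- length(q)
  stopifnot(n >= 1L, length(ages) == n)
  if (anyNA(q) || any(q < 0 | q > 1)) {
    stop("death probabilities must lie in [0, 1]")
  }
  ax <- 0.5
  l <- numeric(n)
  l[1L] <- radix
  if (n > 1L) for (a in 1:(n - 1L)) l[a + 1L] <- l[a] * (1 - q[a])
  d <- l * q
  L <- numeric(n)
  if (n > 1L) {
    L[1:(n - 1L)] <- l[2:n] + ax * d[1:(n - 1L)]
  }
  q_term <- q[n]
  if (l[n] > 0) {
    if (q_term <= 0) {
      stop("terminal death probability is 0: person-years at the open age ",
           "interval are unbounded")
    }
    m_term <- if (q_term >= 1) Inf else -log(1 - q_term)
    L[n] <- if (is.infinite(m_term)) 0 else l[n] / m_term
  } else {
    L[n] <- 0
  }
  T_ <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T_ / l, 0)
  out <- data.frame(age = ages, qx = as.numeric(q), lx = l, dx = d,
                    Lx = L, Tx = T_, ex = e)
  rownames(out) <- NULL
  class(out) <- c("life_table", "data.frame")
  out
}

#' Sullivan decomposition of life expectancy
#'
#' Splits remaining life expectancy at `at_age` into disability-free and
#' disabled components by weighting the life table's person-years with the
#' cross-sectional disability prevalence:
#' `DFLE = sum((1 - pi_a) * L_a) / l_at_age`,
#' `DLE = sum(pi_a * L_a) / l_at_age`. The two components add up to total
#' life expectancy exactly.
#'
#' @param lt A [build_life_table()] result.
#' @param prev Named numeric vector of disability prevalence by age (must
#'   cover every age >= `at_age` with positive person-years).
#' @param at_age Age at which the expectancy is taken.
#' @return A list of class `"sullivan_le"` with elements `at_age`, `total`,
#'   `disability_free`, `disabled` (years) and `proportion_disabled`
#'   (percent).
#' @export
sullivan <- function(lt, prev, at_age) {
  stopifnot(inherits(lt, "life_table"))
  sel <- lt$age >= at_age
  if (!any(sel)) stop("at_age is beyond the life table's age range")
  ages <- lt$age[sel]
  pi_a <- prev[as.character(ages)]
  need <- lt$Lx[sel] > 0
  if (anyNA(pi_a[need])) {
    stop("prevalence missing at contributing age(s): ",
         paste(ages[need & is.na(pi_a)], collapse = ", "))
  }
  pi_a[is.na(pi_a)] <- 0
  if (any(pi_a < 0 | pi_a > 1)) stop("prevalence must lie in [0, 1]")
  l0 <- lt$lx[sel][1L]
  if (l0 <= 0) stop("no survivors at age ", at_age)
  L <- lt$Lx[sel]
  dle <- sum(pi_a * L) / l0
  dfle <- sum((1 - pi_a) * L) / l0
  total <- dfle + dle
  structure(list(
    at_age = at_age,
    total = total,
    disability_free = dfle,
    disabled = dle,
    proportion_disabled = if (total > 0) 100 * dle / total else 0
  ), class = "sullivan_le")
}

#' @export
print.sullivan_le <- function(x, ...) {
  cat(sprintf(
    "<sullivan_le> at age %d: total %.1f y = %.1f disability-free + %.1f disabled (%.1f%% disabled)\n",
    x$at_age, x$total, x$disability_free, x$disabled,
    x$proportion_disabled))
  invisible(x)
}

#' Change in a Sullivan decomposition between two periods
#'
#' @param result_t0,result_t1 Two [sullivan()] results at the same age, or
#'   plain lists with the same fields (so published point estimates can be
#'   differenced with the same conventions).
#' @return Named list with `total`, `disability_free`, `disabled` (years)
#'   and `proportion_disabled` (percentage points); the total change equals
#'   the sum of its two components exactly.
#' @export
decompose_change <- function(result_t0, result_t1) {
  need <- c("at_age", "total", "disability_free", "disabled",
            "proportion_disabled")
  for (r in list(result_t0, result_t1)) {
    if (!is.list(r) || !all(need %in% names(r))) {
      stop("inputs must be sullivan() results or lists with fields: ",
           paste(need, collapse = ", "))
    }
  }
  if (result_t0$at_age != result_t1$at_age) {
    stop("results are at different ages (", result_t0$at_age, " vs ",
         result_t1$at_age, ")")
  }
  list(
    total = result_t1$total - result_t0$total,
    disability_free = result_t1$disability_free - result_t0$disability_free,
    disabled = result_t1$disabled - result_t0$disabled,
    proportion_disabled =
      result_t1$proportion_disabled - result_t0$proportion_disabled
  )
}

#' Sullivan health expectancies for one trajectory year
#'
#' Convenience wrapper: period death probabilities and disability
#' prevalence are taken from the trajectory at `year` (the trajectory must
#' extend one year further to observe the deaths), a life table is built,
#' and the Sullivan split computed.
#'
#' @inheritParams mortality_from_trajectory
#' @param at_age Age at which expectancies are reported (default 65).
#' @return A [sullivan()] result.
#' @export
health_expectancy <- function(traj, year, sex = "all", at_age = 65L) {
  q <- mortality_from_trajectory(traj, year, sex)
  pi_a <- prevalence_from_trajectory(traj, year, sex)
  lt <- build_life_table(q)
  sullivan(lt, pi_a, at_age)
}

#' Health-expectancy summary table
#'
#' Long table mirroring the usual presentation: total, disability-free and
#' disabled life expectancy and the proportion of remaining life lived with
#' disability, by year and sex, with first-vs-last-year differences.
#'
#' @inheritParams disability_count_table
#' @param at_age Age at which expectancies are reported.
#' @return Data frame with columns `year`, `sex`, `measure`, `value`.
#' @export
health_expectancy_table <- function(traj, years = c(2015L, 2025L),
                                    sexes = c("all", "male", "female"),
                                    at_age = 65L) {
  rows <- list()
  for (sx in sexes) {
    res <- lapply(years, function(y) health_expectancy(traj, y, sx, at_age))
    for (k in seq_along(years)) {
      r <- res[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        year = years[k], sex = sx,
        measure = c("total_le", "disability_free_le", "disabled_le",
                    "proportion_disabled_pct"),
        value = c(r$total, r$disability_free, r$disabled,
                  r$proportion_disabled),
        stringsAsFactors = FALSE)
    }
    d <- decompose_change(res[[1L]], res[[length(res)]])
    rows[[length(rows) + 1L]] <- data.frame(
      year = NA_integer_, sex = sx,
      measure = c("total_le_change", "disability_free_le_change",
                  "disabled_le_change", "proportion_disabled_change_pp"),
      value = c(d$total, d$disability_free, d$disabled,
                d$proportion_disabled),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
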