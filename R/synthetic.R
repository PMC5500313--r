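#' Specification of a synthetic input bundle
#'
#' Describes the synthetic stand-ins for the inputs the model consumes in
#' production: a transition-probability schedule, a base-year population by
#' state, an annual entry-cohort series, a standard population, and a
#' sampling distribution for the PSA. Mortality hazards follow Gompertz
#' curves by cause and sex; incidence hazards for CVD, cognitive impairment
#' and disability are logistic in age; calendar trends are baked in through
#' the same trend machinery the scenario layer uses, so generated arc values
#' decay exactly as `(1 - rate)^(year - base_year)`.
#'
#' Default shapes are chosen so the synthetic population is demographically
#' recognisable — disability prevalence rising steeply through old age (of
#' the order of 15% in the late 60s towards a half at 90+), life expectancy
#' at 65 around two decades — without claiming to reproduce any observed
#' cohort.
#'
#' @param age_min,age_max Modelled age range (default 35-100).
#' @param base_year First simulated year (default 2006).
#' @param horizon Last simulated year (default 2025).
#' @param gompertz_mortality List with elements `noncvd` and `cvd`, each
#'   `list(alpha = c(male=, female=), beta =)`: baseline hazard at
#'   `age_min` and log-slope per year of age.
#' @param incidence_shapes List with elements `cvd`, `ci`, `dis`, each
#'   `list(max = c(male=, female=), mid =, slope =)`: logistic-in-age
#'   hazard plateau, midpoint age and steepness.
#' @param risk_multipliers Hazard ratios linking states: CVD death given
#'   CVD; non-CVD death given disability / dementia; disability incidence
#'   given CVD / cognitive impairment; cognitive-impairment incidence given
#'   CVD.
#' @param dementia_trend Relative annual decline in dementia incidence
#'   (default 0.027).
#' @param cvd_trend Relative annual decline applied to both CVD incidence
#'   and CVD mortality (default 0.02).
#' @param noncvd_trend Relative annual decline in non-CVD mortality
#'   (default 0).
#' @param base_prevalence `list(cvd, ci, dis)`, each `c(mid =, slope =)`
#'   logistic parameters for base-year prevalence by age.
#' @param cohort_size Entrants per year per sex at `age_min` (default
#'   190 000, of the order of a national single-year birth cohort).
#' @param ess Dirichlet effective sample size for the PSA distribution.
#' @param seed Integer seed recorded in the bundle's provenance (generation
#'   itself is deterministic).
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(age_min = 35L, age_max = 100L,
                           base_year = 2006L, horizon = 2025L,
                           gompertz_mortality = list(
                             noncvd = list(alpha = c(male = 5.2e-4,
                                                     female = 3.6e-4),
                                           beta = 0.092),
                             cvd = list(alpha = c(male = 1.6e-4,
                                                  female = 0.8e-4),
                                        beta = 0.1)
                           ),
                           incidence_shapes = list(
                             cvd = list(max = c(male = 0.026,
                                                female = 0.018),
                                        mid = 78, slope = 0.07),
                             ci = list(max = c(male = 0.05,
                                               female = 0.055),
                                       mid = 87, slope = 0.09),
                             dis = list(max = c(male = 0.12,
                                                female = 0.14),
                                        mid = 92, slope = 0.085)
                           ),
                           risk_multipliers = c(
                             cvd_death_given_cvd = 4,
                             death_given_disability = 2.6,
                             death_given_dementia = 3.6,
                             dis_given_cvd = 1.5,
                             dis_given_ci = 2.0,
                             ci_given_cvd = 1.3
                           ),
                           dementia_trend = 0.027,
                           cvd_trend = 0.02,
                           noncvd_trend = 0,
                           base_prevalence = list(
                             cvd = c(mid = 97, slope = 0.062),
                             ci = c(mid = 96, slope = 0.094),
                             dis = c(mid = 89, slope = 0.0912)
                           ),
                           cohort_size = 190000,
                           ess = 1000,
                           seed = 1L) {
  for (cause in c("noncvd", "cvd")) {
    g <- gompertz_mortality[[cause]]
    if (any(g$alpha <= 0) || g$beta <= 0) {
      stop("gompertz_mortality$", cause,
           ": hazards must be positive (alpha > 0, beta > 0)")
    }
  }
  for (inc in c("cvd", "ci", "dis")) {
    if (any(incidence_shapes[[inc]]$max < 0)) {
      stop("incidence_shapes$", inc, "$max must be non-negative")
    }
  }
  if (any(risk_multipliers <= 0)) stop("risk multipliers must be positive")
  if (cohort_size < 0) stop("cohort_size must be non-negative")
  structure(list(
    age_min = as.integer(age_min), age_max = as.integer(age_max),
    base_year = as.integer(base_year), horizon = as.integer(horizon),
    gompertz_mortality = gompertz_mortality,
    incidence_shapes = incidence_shapes,
    risk_multipliers = risk_multipliers,
    dementia_trend = dementia_trend, cvd_trend = cvd_trend,
    noncvd_trend = noncvd_trend,
    base_prevalence = base_prevalence,
    cohort_size = cohort_size, ess = ess, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# hazard -> one-year probability
.h2p <- function(h) 1 - exp(-h)

.logistic <- function(age, mid, slope) 1 / (1 + exp(-slope * (age - mid)))

# base-year transition matrix for one (age, sex): gains only, competing
# death causes split proportionally to their hazards, row sums exactly 1
.base_matrix <- function(spec, age, sex) {
  st <- health_states()
  mul <- spec$risk_multipliers
  gm <- spec$gompertz_mortality
  inc <- spec$incidence_shapes
  rel_age <- age - spec$age_min
  h_non0 <- gm$noncvd$alpha[[sex]] * exp(gm$noncvd$beta * rel_age)
  h_cvd0 <- gm$cvd$alpha[[sex]] * exp(gm$cvd$beta * rel_age)
  h_inc <- function(shape) {
    shape$max[[sex]] * .logistic(age, shape$mid, shape$slope)
  }
  P <- matrix(0, 10L, 10L, dimnames = list(state_codes(), state_codes()))
  P[9L, 9L] <- 1; P[10L, 10L] <- 1
  for (i in 1:8) {
    has_cvd <- st$has_cvd[i]
    has_ci <- st$has_cognitive_impairment[i]
    has_dis <- st$has_disability[i]
    has_dem <- st$has_dementia[i]
    frailty <- if (has_dem) mul[["death_given_dementia"]] else
      if (has_dis) mul[["death_given_disability"]] else 1
    hc <- h_cvd0 * (if (has_cvd) mul[["cvd_death_given_cvd"]] else 1) * frailty
    hn <- h_non0 * frailty
    p_death <- .h2p(hc + hn)
    P[i, 9L] <- p_death * hc / (hc + hn)
    P[i, 10L] <- p_death * hn / (hc + hn)
    surv <- 1 - p_death
    p_gain <- c(
      cvd = if (has_cvd) NA else
        .h2p(h_inc(inc$cvd)),
      ci = if (has_ci) NA else
        .h2p(h_inc(inc$ci) * (if (has_cvd) mul[["ci_given_cvd"]] else 1)),
      dis = if (has_dis) NA else
        .h2p(h_inc(inc$dis) *
               (if (has_cvd) mul[["dis_given_cvd"]] else 1) *
               (if (has_ci) mul[["dis_given_ci"]] else 1))
    )
    for (j in 1:8) {
      # reachable by gaining attributes only (no remission in the generator)
      gains_cvd <- st$has_cvd[j] && !has_cvd
      gains_ci <- st$has_cognitive_impairment[j] && !has_ci
      gains_dis <- st$has_disability[j] && !has_dis
      loses <- (!st$has_cvd[j] && has_cvd) ||
        (!st$has_cognitive_impairment[j] && has_ci) ||
        (!st$has_disability[j] && has_dis)
      if (loses) next
      pr <- surv
      if (!has_cvd) pr <- pr * (if (gains_cvd) p_gain[["cvd"]] else 1 - p_gain[["cvd"]])
      if (!has_ci) pr <- pr * (if (gains_ci) p_gain[["ci"]] else 1 - p_gain[["ci"]])
      if (!has_dis) pr <- pr * (if (gains_dis) p_gain[["dis"]] else 1 - p_gain[["dis"]])
      P[i, j] <- pr
    }
  }
  P
}

#' Generate a coherent synthetic input bundle
#'
#' Builds every input the projection pipeline needs from a
#' [synthetic_spec()]: a trended transition schedule (base-year matrices
#' from the spec's hazards, calendar trends applied via [apply_trends()] so
#' the construction identities hold exactly), a base-year population
#' consistent with the spec's prevalence curves, a constant entry-cohort
#' series extending one year past the horizon, a smoothly declining
#' standard population, and a Dirichlet [parameter_distribution()]. The
#' bundle is deterministic given the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `"input_bundle"` with elements `schedule`,
#'   `initial`, `entrants`, `std`, `dist` and `spec`.
#' @export
generate_inputs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ages <- spec$age_min:spec$age_max
  sexes <- c("male", "female")
  years <- spec$base_year:spec$horizon
  na <- length(ages)

  base <- array(NA_real_, c(na, 2L, 10L, 10L))
  for (s in 1:2) for (a in seq_len(na)) {
    base[a, s, , ] <- .base_matrix(spec, ages[a], sexes[s])
  }
  if (anyNA(base) || any(base < 0) || any(base > 1)) {
    k <- which(is.na(base) | base < 0 | base > 1, arr.ind = TRUE)[1L, ]
    stop("generated probability outside [0, 1] at age ", ages[k[1L]],
         ", sex ", sexes[k[2L]],
         "; the specified hazards are too large to combine")
  }
  flat <- constant_schedule(base, ages, sexes, years)
  tspec <- trend_spec(
    dementia_annual_decline = spec$dementia_trend,
    cvd_mortality_annual_decline = spec$cvd_trend,
    noncvd_mortality_annual_decline = spec$noncvd_trend,
    base_year = spec$base_year
  )
  schedule <- apply_trends(flat, tspec)

  # base-year population: cohort survival shape x independent prevalence mix
  bp <- spec$base_prevalence
  counts <- array(0, c(na, 2L, 10L))
  st <- health_states()
  for (s in 1:2) {
    p_cvd <- .logistic(ages, bp$cvd[["mid"]], bp$cvd[["slope"]])
    p_ci <- .logistic(ages, bp$ci[["mid"]], bp$ci[["slope"]])
    p_dis <- .logistic(ages, bp$dis[["mid"]], bp$dis[["slope"]])
    # survivorship under the state-mix-weighted death probability, so the
    # age pyramid thins realistically where disability and dementia raise
    # mortality
    shares <- sapply(1:8, function(j) {
      (if (st$has_cvd[j]) p_cvd else 1 - p_cvd) *
        (if (st$has_cognitive_impairment[j]) p_ci else 1 - p_ci) *
        (if (st$has_disability[j]) p_dis else 1 - p_dis)
    })
    surv <- numeric(na); surv[1L] <- 1
    for (a in seq_len(na - 1L)) {
      p_death_states <- rowSums(.base_matrix(spec, ages[a], sexes[s])[1:8, 9:10])
      surv[a + 1L] <- surv[a] * (1 - sum(shares[a, ] * p_death_states))
    }
    n_age <- spec$cohort_size * surv
    for (j in 1:8) {
      share <- (if (st$has_cvd[j]) p_cvd else 1 - p_cvd) *
        (if (st$has_cognitive_impairment[j]) p_ci else 1 - p_ci) *
        (if (st$has_disability[j]) p_dis else 1 - p_dis)
      counts[, s, j] <- n_age * share
    }
  }
  initial <- population_tensor(counts, spec$base_year, ages, sexes)

  entrants <- entry_cohorts(spec$base_year:(spec$horizon + 1L),
                            spec$cohort_size)

  # smooth declining age pyramid following the generated survivorship, so
  # old ages carry realistic weight; absolute scale is irrelevant under
  # direct standardisation
  w <- counts[, , 1:8]
  std <- standard_population(cbind(rowSums(w[, 1L, ]), rowSums(w[, 2L, ])),
                             ages)

  dist <- parameter_distribution(schedule, spec$ess)

  structure(list(schedule = schedule, initial = initial,
                 entrants = entrants, std = std, dist = dist, spec = spec),
            class = "input_bundle")
}

#' @export
print.input_bundle <- function(x, ...) {
  cat("<input_bundle>\n")
  print(x$schedule)
  print(x$initial)
  cat("  entrants/year/sex:", format(x$spec$cohort_size), "\n")
  invisible(x)
}

#' Recover a calendar trend from a schedule
#'
#' Estimates the relative annual decline of an incidence arc class by a
#' log-linear fit of arc probability against calendar year, pooled over all
#' pure arcs of the class (arcs that simultaneously belong to the other
#' incidence class carry the product of two trends and are excluded) with a
#' separate intercept per (age, sex, arc) cell. Observations are weighted
#' by the arc probability itself — the inverse of the log-scale sampling
#' variance under row-wise Dirichlet noise — so tiny arcs with wild
#' logarithms do not dominate or bias the slope. Returns `1 - exp(slope)`;
#' on a noiselessly constructed schedule the recovery is exact.
#'
#' @param schedule A [transition_schedule()] covering at least 3 years.
#' @param arc_class `"dementia_incidence"` or `"cvd_incidence"`.
#' @return Estimated proportion per year.
#' @export
recover_trend <- function(schedule,
                          arc_class = c("dementia_incidence",
                                        "cvd_incidence")) {
  stopifnot(inherits(schedule, "transition_schedule"))
  arc_class <- match.arg(arc_class)
  if (length(schedule$years) < 3L) {
    stop("at least 3 calendar years are needed to fit a trend")
  }
  classes <- arc_classes()
  other <- setdiff(c("dementia_incidence", "cvd_incidence"), arc_class)
  pure <- classes[[arc_class]] & !classes[[other]]
  arcs <- which(pure, arr.ind = TRUE)
  x <- schedule$years
  num <- 0; den <- 0
  n_cells <- 0L; n_zero <- 0L
  for (k in seq_len(nrow(arcs))) {
    f <- arcs[k, 1L]; t <- arcs[k, 2L]
    for (s in seq_along(schedule$sexes)) {
      V <- schedule$p[, s, , f, t, drop = FALSE]
      dim(V) <- c(length(schedule$ages), length(schedule$years))
      ok <- rowSums(V <= 0) == 0L
      n_zero <- n_zero + sum(V[!ok, , drop = FALSE] <= 0)
      V <- V[ok, , drop = FALSE]
      if (nrow(V) == 0L) next
      n_cells <- n_cells + nrow(V)
      L <- log(V)
      for (r in seq_len(nrow(V))) {
        w <- V[r, ]
        xb <- sum(w * x) / sum(w)
        lb <- sum(w * L[r, ]) / sum(w)
        num <- num + sum(w * (L[r, ] - lb) * (x - xb))
        den <- den + sum(w * (x - xb)^2)
      }
    }
  }
  if (n_zero > 0L) {
    warning(n_zero, " zero arc value(s) excluded from the log-linear fit")
  }
  if (n_cells == 0L) {
    stop("no strictly positive arcs of class ", arc_class, " to fit")
  }
  1 - exp(num / den)
}
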