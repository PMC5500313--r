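#' Parameter distribution over transition rows
#'
#' Dirichlet sampling distribution for the probabilistic sensitivity
#' analysis: each (age, sex, year, from-state) row of the central schedule
#' is the mean of a Dirichlet distribution with concentration
#' `central_row * ess`. Larger effective sample sizes concentrate sampled
#' rows around the central values (deviations shrink as ess^(-1/2)); arcs
#' that are 0 in the central schedule (masked arcs, forbidden remissions)
#' remain exactly 0 in every draw, and identity death rows are reproduced
#' exactly.
#'
#' @param central A valid [transition_schedule()] (the point-estimate
#'   schedule).
#' @param ess Effective sample size: positive scalar, or an array over
#'   `[age, sex, year, from]` for row-specific dispersion. `Inf` gives the
#'   degenerate (zero-dispersion) distribution.
#' @return An object of class `"parameter_distribution"`.
#' @export
parameter_distribution <- function(central, ess = 1000) {
  stopifnot(inherits(central, "transition_schedule"))
  rep_ <- validate_schedule(central)
  if (nrow(rep_) > 0L) {
    stop("central schedule fails validation (",
         paste(unique(rep_$issue), collapse = ", "), ")")
  }
  dn <- dim(central$p)[1:4]
  if (length(ess) == 1L) {
    if (is.na(ess) || ess <= 0) stop("ess must be positive")
  } else {
    if (!all(dim(ess) == dn)) {
      stop("ess array must have dim [age, sex, year, from]")
    }
    if (anyNA(ess) || any(ess <= 0)) stop("ess values must be positive")
  }
  structure(list(central = central, ess = ess),
            class = "parameter_distribution")
}

#' @export
print.parameter_distribution <- function(x, ...) {
  e <- x$ess
  cat("<parameter_distribution> Dirichlet rows, ess ",
      if (length(e) == 1L) format(e) else
        sprintf("[%g, %g]", min(e), max(e)),
      "\n", sep = "")
  print(x$central)
  invisible(x)
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one transition schedule from a parameter distribution
#'
#' Row-wise Dirichlet sampling via normalised gamma variates: reproducible
#' given `seed`, exact zeros on zero-probability arcs, valid stochastic rows
#' by construction.
#'
#' @param dist A [parameter_distribution()].
#' @param seed Integer seed.
#' @return A [transition_schedule()] passing [validate_schedule()].
#' @export
sample_schedule <- function(dist, seed) {
  stopifnot(inherits(dist, "parameter_distribution"))
  central <- dist$central
  if (length(dist$ess) == 1L && is.infinite(dist$ess)) return(central)
  p <- central$p
  dn <- dim(p)
  ess <- dist$ess
  alpha <- if (length(ess) == 1L) {
    p * ess
  } else {
    p * as.vector(ess)  # broadcast over the trailing `to` dimension
  }
  g <- .with_seed(seed, {
    draws <- numeric(length(alpha))
    pos <- alpha > 0
    draws[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
    draws
  })
  gm <- matrix(g, ncol = 10L)
  rs <- rowSums(gm)
  # an all-positive Dirichlet row sums to > 0 almost surely; guard anyway
  bad <- rs <= 0
  if (any(bad)) {
    cm <- matrix(p, ncol = 10L)
    gm[bad, ] <- cm[bad, ]
    rs[bad] <- 1
  }
  gm <- gm / rs
  sampled <- array(gm, dn)
  transition_schedule(sampled, central$ages, central$sexes, central$years)
}

# deterministic, order-insensitive child seed for iteration i (counter-based
# splitting; keeps values inside the 32-bit integer range)
.child_seed <- function(master_seed, i) {
  a <- (as.double(master_seed) %% 2147483647) + 1
  x <- (a * 48271) %% 2147483647
  x <- (x + as.double(i) * 69621) %% 2147483647
  x <- (x * 16807) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

#' Default PSA output set
#'
#' The headline quantities collected per iteration: disability cases and
#' age-standardised prevalence in the 65+ band at the report years, their
#' relative change, and the Sullivan decomposition at age 65.
#'
#' @param traj A trajectory (must extend one year past the last report year
#'   for the life-table step).
#' @param config A [scenario_config()] providing `std` and `report_years`.
#' @return Named numeric vector.
#' @export
psa_outputs_default <- function(traj, config) {
  y0 <- config$report_years[1L]
  y1 <- config$report_years[length(config$report_years)]
  c0 <- disability_count(traj, y0, c(65, Inf), "all", "all")
  c1 <- disability_count(traj, y1, c(65, Inf), "all", "all")
  s0 <- health_expectancy(traj, y0, "all", 65L)
  s1 <- health_expectancy(traj, y1, "all", 65L)
  out <- c(
    disability_cases_65plus_thousands_y0 = c0,
    disability_cases_65plus_thousands_y1 = c1,
    disability_cases_65plus_relative_change_pct = relative_change(c0, c1),
    std_prevalence_65plus_pct_y0 =
      age_standardised_prevalence(traj, y0, config$std, c(65, Inf), "all"),
    std_prevalence_65plus_pct_y1 =
      age_standardised_prevalence(traj, y1, config$std, c(65, Inf), "all"),
    le65_total_y0 = s0$total,
    le65_total_y1 = s1$total,
    le65_disability_free_y0 = s0$disability_free,
    le65_disability_free_y1 = s1$disability_free,
    le65_disabled_y0 = s0$disabled,
    le65_disabled_y1 = s1$disabled,
    le65_proportion_disabled_pct_y0 = s0$proportion_disabled,
    le65_proportion_disabled_pct_y1 = s1$proportion_disabled
  )
  names(out) <- sub("_y0$", paste0("_", y0), names(out))
  names(out) <- sub("_y1$", paste0("_", y1), names(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of transition-probability uncertainty: for each
#' iteration a schedule is drawn from `dist` under a deterministically
#' derived child seed, the projection and summary pipeline is rerun, and
#' 95% uncertainty intervals are formed from the 2.5th and 97.5th
#' percentiles (linear-interpolation quantiles) of the iteration outputs.
#' The point estimate is the central (unsampled) run, not the iteration
#' mean.
#'
#' @param dist A [parameter_distribution()].
#' @param config A [scenario_config()] carrying the initial population,
#'   entry cohorts, standard population, horizon and report years.
#' @param n_iter Number of iterations (default 1000, minimum 2).
#' @param master_seed Integer master seed; child seeds are derived by a
#'   counter-based splitting scheme so iterations are order-insensitive.
#' @param outputs_fn Function `(trajectory, config) -> named numeric`
#'   computing the outputs to summarise (default [psa_outputs_default()]).
#' @return An object of class `"psa_result"`: data frame with columns
#'   `key`, `point`, `lower`, `upper`, and attributes `n_iter`,
#'   `master_seed` and the per-iteration `draws` matrix.
#' @export
run_psa <- function(dist, config, n_iter = 1000L, master_seed = 1L,
                    outputs_fn = psa_outputs_default) {
  stopifnot(inherits(dist, "parameter_distribution"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 2L) stop("n_iter must be >= 2")
  run_one <- function(schedule) {
    traj <- run_projection(config$initial, schedule, config$entrants,
                           config$run_horizon)
    outputs_fn(traj, config)
  }
  point <- run_one(dist$central)
  draws <- matrix(NA_real_, n_iter, length(point),
                  dimnames = list(NULL, names(point)))
  seeds <- vapply(seq_len(n_iter), function(i) .child_seed(master_seed, i),
                  integer(1))
  for (i in seq_len(n_iter)) {
    res <- tryCatch(
      run_one(sample_schedule(dist, seeds[i])),
      error = function(e) {
        stop("PSA iteration ", i, " (seed ", seeds[i], ") failed: ",
             conditionMessage(e), call. = FALSE)
      })
    draws[i, ] <- res
  }
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  out <- data.frame(key = names(point), point = as.numeric(point),
                    lower = qs[1L, ], upper = qs[2L, ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("psa_result", "data.frame"),
            n_iter = n_iter, master_seed = master_seed, seeds = seeds,
            draws = draws)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", attr(x, "n_iter"), "iterations, master seed",
      attr(x, "master_seed"), "\n")
  df <- data.frame(key = x$key,
                   point = signif(x$point, 6),
                   lo95 = signif(x$lower, 6),
                   hi95 = signif(x$upper, 6))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
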