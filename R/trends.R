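#' Calendar-trend specification
#'
#' Relative annual declines applied to the incidence and mortality arc
#' classes of a base schedule. A rate r maps calendar year y to the
#' multiplier (1 - r)^(y - base_year), so positive rates are declines and
#' negative rates growth. The dementia-incidence default is a 2.7% relative
#' annual decline; CVD incidence is assumed to parallel the decline in CVD
#' mortality, so when `cvd_incidence_annual_decline` is not given it is set
#' equal to `cvd_mortality_annual_decline`.
#'
#' @param dementia_annual_decline Proportion per year (default 0.027).
#' @param cvd_mortality_annual_decline Proportion per year. No default: the
#'   tie between CVD incidence and CVD mortality makes this a required,
#'   deliberately user-stated quantity.
#' @param cvd_incidence_annual_decline Proportion per year; defaults to the
#'   CVD mortality decline.
#' @param noncvd_mortality_annual_decline Proportion per year (default 0).
#' @param base_year Calendar year at which every factor equals 1.
#' @return A list of class `"trend_spec"`.
#' @export
trend_spec <- function(dementia_annual_decline = 0.027,
                       cvd_mortality_annual_decline,
                       cvd_incidence_annual_decline = NULL,
                       noncvd_mortality_annual_decline = 0,
                       base_year) {
  if (missing(cvd_mortality_annual_decline)) {
    stop("cvd_mortality_annual_decline must be supplied (CVD incidence ",
         "is tied to the CVD mortality decline and has no default)")
  }
  if (is.null(cvd_incidence_annual_decline)) {
    cvd_incidence_annual_decline <- cvd_mortality_annual_decline
  }
  rates <- c(dementia = dementia_annual_decline,
             cvd_incidence = cvd_incidence_annual_decline,
             cvd_mortality = cvd_mortality_annual_decline,
             noncvd_mortality = noncvd_mortality_annual_decline)
  if (any(!is.finite(rates)) || any(rates < -0.5 | rates > 0.5)) {
    stop("annual decline rates must lie in [-0.5, 0.5]; got: ",
         paste(sprintf("%s=%g", names(rates), rates), collapse = ", "))
  }
  structure(list(
    dementia_annual_decline = dementia_annual_decline,
    cvd_incidence_annual_decline = cvd_incidence_annual_decline,
    cvd_mortality_annual_decline = cvd_mortality_annual_decline,
    noncvd_mortality_annual_decline = noncvd_mortality_annual_decline,
    base_year = as.integer(base_year)
  ), class = "trend_spec")
}

#' Named dementia-trend scenario presets
#'
#' `"baseline"` assumes a 2.7% relative annual decline in dementia
#' incidence, `"constant"` no decline, and `"fast"` a 4% decline. The CVD
#' rates are passed through unchanged.
#'
#' @param name Scenario name.
#' @inheritParams trend_spec
#' @return A [trend_spec()].
#' @export
trend_preset <- function(name = c("baseline", "constant", "fast"),
                         cvd_mortality_annual_decline, base_year,
                         noncvd_mortality_annual_decline = 0) {
  name <- match.arg(name)
  dem <- switch(name, baseline = 0.027, constant = 0.0, fast = 0.04)
  trend_spec(
    dementia_annual_decline = dem,
    cvd_mortality_annual_decline = cvd_mortality_annual_decline,
    noncvd_mortality_annual_decline = noncvd_mortality_annual_decline,
    base_year = base_year
  )
}

#' @export
print.trend_spec <- function(x, ...) {
  cat("<trend_spec> base year", x$base_year, "\n")
  cat(sprintf("  dementia incidence decline: %.3f/yr\n",
              x$dementia_annual_decline))
  cat(sprintf("  CVD incidence decline:      %.3f/yr\n",
              x$cvd_incidence_annual_decline))
  cat(sprintf("  CVD mortality decline:      %.3f/yr\n",
              x$cvd_mortality_annual_decline))
  cat(sprintf("  non-CVD mortality decline:  %.3f/yr\n",
              x$noncvd_mortality_annual_decline))
  invisible(x)
}

#' Calendar-trend multiplier
#'
#' @param rate Relative annual decline (proportion per year).
#' @param year Calendar year.
#' @param base_year Year at which the multiplier is 1.
#' @return `(1 - rate)^(year - base_year)`.
#' @export
#' @examples
#' trend_factor(0.027, 2016, 2006)  # 0.973^10
trend_factor <- function(rate, year, base_year) {
  if (any(year < base_year)) {
    stop("year (", paste(year[year < base_year], collapse = ", "),
         ") precedes base_year (", base_year, ")")
  }
  (1 - rate)^(year - base_year)
}

#' Apply calendar trends to a transition schedule
#'
#' Scales the classified arc families of `base` (see [arc_classes()]) by
#' their trend multipliers year by year, then restores row-stochasticity by
#' assigning the residual entirely to each row's self-transition: people who
#' avoid an incident event remain in their current state. Arcs belonging to
#' two families (simultaneous CVD and dementia acquisition) receive the
#' product of both factors.
#'
#' With `scale_on = "probability"` (default) probabilities are multiplied by
#' the factor directly. With `scale_on = "hazard"` the factor scales the
#' implied hazard instead: p' = 1 - (1 - p)^factor, a sensitivity variant
#' that matters only in second order for the small annual probabilities
#' involved.
#'
#' @param base A valid [transition_schedule()]. The schedule's years must
#'   not precede `spec$base_year`.
#' @param spec A [trend_spec()].
#' @param scale_on `"probability"` or `"hazard"`.
#' @return A [transition_schedule()] that passes [validate_schedule()].
#' @export
apply_trends <- function(base, spec,
                         scale_on = c("probability", "hazard")) {
  stopifnot(inherits(base, "transition_schedule"),
            inherits(spec, "trend_spec"))
  scale_on <- match.arg(scale_on)
  classes <- arc_classes()
  rates <- c(dementia_incidence = spec$dementia_annual_decline,
             cvd_incidence = spec$cvd_incidence_annual_decline,
             cvd_mortality = spec$cvd_mortality_annual_decline,
             noncvd_mortality = spec$noncvd_mortality_annual_decline)
  p <- base$p
  na <- length(base$ages); ns <- length(base$sexes)
  codes <- state_codes()
  alive_idx <- .state_index(alive_states())
  for (yi in seq_along(base$years)) {
    year <- base$years[yi]
    fmat <- matrix(1, 10L, 10L)
    for (cl in names(classes)) {
      f <- trend_factor(rates[[cl]], year, spec$base_year)
      fmat[classes[[cl]]] <- fmat[classes[[cl]]] * f
    }
    fbig <- array(rep(fmat, each = na * ns), c(na, ns, 10L, 10L))
    block <- p[, , yi, , , drop = FALSE]
    dim(block) <- c(na, ns, 10L, 10L)
    if (scale_on == "probability") {
      block <- block * fbig
    } else {
      scaled <- 1 - (1 - block)^fbig
      keep <- fbig == 1
      block[!keep] <- scaled[!keep]
    }
    # self-transition absorbs the residual for alive rows
    for (i in alive_idx) {
      off <- block[, , i, -i, drop = FALSE]
      resid <- 1 - array(rowSums(matrix(off, ncol = 9L)), c(na, ns))
      bad <- resid < -1e-12
      if (any(bad)) {
        k <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf(
          paste0("trend scaling drives the self-transition of %s below 0 ",
                 "at age %d, sex %s, year %d (residual %.6g); the base ",
                 "probabilities are inconsistent with the requested trends"),
          codes[i], base$ages[k[1L]], base$sexes[k[2L]], year,
          resid[k[1L], k[2L]]))
      }
      block[, , i, i] <- pmax(resid, 0)
    }
    p[, , yi, , ] <- block
  }
  out <- transition_schedule(p, base$ages, base$sexes, base$years)
  rep_ <- validate_schedule(out)
  if (nrow(rep_) > 0L) {
    stop("trended schedule failed validation: ",
         paste(utils::head(unique(rep_$issue), 3L), collapse = ", "))
  }
  out
}
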