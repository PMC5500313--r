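#' Standard population for direct age standardisation
#'
#' @param weights Numeric matrix `[age, sex]` of reference-population person
#'   counts (conventionally the 2015 population), all >= 0 with at least one
#'   positive weight.
#' @param ages Integer age vector.
#' @param sexes Character vector of sexes.
#' @return Matrix of class `"standard_population"`.
#' @export
standard_population <- function(weights, ages,
                                sexes = c("male", "female")) {
  ages <- as.integer(ages)
  if (!is.matrix(weights)) {
    weights <- matrix(weights, nrow = length(ages), ncol = length(sexes))
  }
  if (nrow(weights) != length(ages) || ncol(weights) != length(sexes)) {
    stop("weights must be an [age x sex] matrix")
  }
  if (anyNA(weights) || any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative with at least one positive entry")
  }
  dimnames(weights) <- list(age = as.character(ages), sex = sexes)
  structure(weights, class = c("standard_population", "matrix", "array"))
}

# internal: resolve an age band like c(65, Inf), "65+", "65-84" to ages
.band_ages <- function(ages, band) {
  if (is.character(band)) {
    band <- if (grepl("\\+$", band)) {
      c(as.integer(sub("\\+$", "", band)), Inf)
    } else {
      as.integer(strsplit(band, "-", fixed = TRUE)[[1]])
    }
  }
  if (length(band) == 1L) band <- c(band, band)
  sel <- ages >= band[1L] & ages <= band[2L]
  if (!any(sel)) stop("empty age band: no modelled ages in [",
                      band[1L], ", ", band[2L], "]")
  sel
}

# internal: sex column selection ("all" -> every sex)
.sex_sel <- function(sexes, sex) {
  if (identical(sex, "all")) return(rep(TRUE, length(sexes)))
  sel <- sexes %in% sex
  if (!any(sel)) stop("unknown sex selection: ", paste(sex, collapse = ", "))
  sel
}

# internal: state columns matching a disability type selection
.dtype_states <- function(dtype) {
  st <- health_states()
  if (identical(dtype, "all")) {
    which(st$alive & st$disability_type != "NONE")
  } else {
    if (!all(dtype %in% disability_types())) {
      stop("unknown disability type: ", paste(dtype, collapse = ", "))
    }
    which(st$alive & st$disability_type %in% dtype)
  }
}

#' Number of people living with disability, in thousands
#'
#' Sums occupancy over the disabled states matching `dtype` within the age
#' band and sex selection of one trajectory year.
#'
#' @param traj A trajectory from [run_projection()].
#' @param year Calendar year.
#' @param ages Age band: `c(lo, hi)`, `"65+"` or `"65-84"` style strings.
#' @param sex `"all"`, `"male"` or `"female"`.
#' @param dtype `"all"` (any disability) or one or more disability-type
#'   labels from [disability_types()].
#' @return Persons, in thousands.
#' @export
disability_count <- function(traj, year, ages = c(65, Inf), sex = "all",
                             dtype = "all") {
  tn <- trajectory_year(traj, year)
  asel <- .band_ages(tn$ages, ages)
  ssel <- .sex_sel(tn$sexes, sex)
  states <- .dtype_states(dtype)
  sum(tn$counts[asel, ssel, states, drop = FALSE]) / 1000
}

#' Crude and directly age-standardised disability prevalence
#'
#' Direct standardisation over the single-year (age, sex) grid:
#' `100 * sum(w_as * prev_as) / sum(w_as)` where `prev_as` is the proportion
#' disabled among the alive at each age and sex in the trajectory year.
#' Ages with positive weight but zero alive population have undefined
#' prevalence and are excluded from both sums with a warning.
#'
#' @inheritParams disability_count
#' @param std A [standard_population()] (its age range must cover the band).
#' @return Prevalence in percent.
#' @export
age_standardised_prevalence <- function(traj, year, std,
                                        ages = c(65, Inf), sex = "all") {
  stopifnot(inherits(std, "standard_population"))
  tn <- trajectory_year(traj, year)
  std_ages <- as.integer(rownames(std))
  if (!all(tn$ages %in% std_ages) && !all(std_ages %in% tn$ages)) {
    stop("standard population does not align with the trajectory ages")
  }
  asel <- .band_ages(tn$ages, ages)
  ssel <- .sex_sel(tn$sexes, sex)
  dis_states <- .dtype_states("all")
  ages_used <- tn$ages[asel]

  num <- 0; den <- 0; dropped <- character()
  for (s in which(ssel)) {
    alive <- rowSums(matrix(tn$counts[asel, s, 1:8], nrow = sum(asel)))
    disab <- rowSums(matrix(tn$counts[asel, s, dis_states],
                            nrow = sum(asel)))
    w <- std[match(ages_used, std_ages), s]
    undef <- alive == 0 & w > 0
    if (any(undef)) {
      dropped <- c(dropped, paste0(tn$sexes[s], ":", ages_used[undef]))
      w[undef] <- 0
    }
    ok <- alive > 0
    num <- num + sum(w[ok] * disab[ok] / alive[ok])
    den <- den + sum(w)
  }
  if (length(dropped) > 0L) {
    warning("zero alive population at weighted age(s) ",
            paste(dropped, collapse = ", "),
            "; excluded from the standardisation")
  }
  if (den == 0) stop("standard population has zero total weight in the band")
  100 * num / den
}

#' Relative change between two quantities, in percent
#'
#' @param v0 Baseline value (> 0).
#' @param v1 Comparison value.
#' @return `(v1 - v0) / v0 * 100`.
#' @export
#' @examples
#' relative_change(2251, 2811)
relative_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("relative change requires a positive baseline")
  (v1 - v0) / v0 * 100
}

#' Geometric annual relative change, in percent per year
#'
#' @inheritParams relative_change
#' @param years Number of years between the two values (>= 1).
#' @return `((v1 / v0)^(1 / years) - 1) * 100`.
#' @export
annual_relative_change <- function(v0, v1, years) {
  if (any(v0 <= 0)) stop("annual relative change requires a positive baseline")
  if (any(years < 1)) stop("years must be >= 1")
  ((v1 / v0)^(1 / years) - 1) * 100
}

#' Compare a model summary table against a reference table
#'
#' Join on the shared key columns and report absolute and relative
#' differences per key. Keys present in only one table are listed, not
#' fatal. This is the machinery used to confront model output with external
#' observed series (which the user supplies).
#'
#' @param model,reference Data frames with identical key columns and one
#'   `value` column.
#' @param keys Character vector of key column names (default: every shared
#'   column except `value`).
#' @return A list of class `"comparison_report"` with elements `matched`
#'   (data frame with `value_model`, `value_reference`, `abs_diff`,
#'   `rel_diff`), `only_model` and `only_reference` (key data frames).
#' @export
compare_series <- function(model, reference, keys = NULL) {
  stopifnot(is.data.frame(model), is.data.frame(reference),
            "value" %in% names(model), "value" %in% names(reference))
  if (is.null(keys)) {
    keys <- setdiff(intersect(names(model), names(reference)), "value")
  }
  if (length(keys) == 0L) stop("no shared key columns to join on")
  mk <- do.call(paste, c(model[keys], sep = "\r"))
  rk <- do.call(paste, c(reference[keys], sep = "\r"))
  common <- intersect(mk, rk)
  mi <- match(common, mk); ri <- match(common, rk)
  matched <- model[mi, keys, drop = FALSE]
  matched$value_model <- model$value[mi]
  matched$value_reference <- reference$value[ri]
  matched$abs_diff <- matched$value_model - matched$value_reference
  matched$rel_diff <- ifelse(matched$value_reference != 0,
                             matched$abs_diff / matched$value_reference, NA)
  rownames(matched) <- NULL
  structure(list(
    matched = matched,
    only_model = unique(model[!(mk %in% rk), keys, drop = FALSE]),
    only_reference = unique(reference[!(rk %in% mk), keys, drop = FALSE])
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", nrow(x$matched), "matched key(s)")
  if (nrow(x$matched) > 0L) {
    cat(sprintf("; max |rel diff| %.4g",
                max(abs(x$matched$rel_diff), na.rm = TRUE)))
  }
  cat("\n")
  if (nrow(x$only_model) > 0L) {
    cat("  keys only in model:", nrow(x$only_model), "\n")
  }
  if (nrow(x$only_reference) > 0L) {
    cat("  keys only in reference:", nrow(x$only_reference), "\n")
  }
  invisible(x)
}

#' Disability-case summary table
#'
#' Long table of disability counts (thousands) by year, sex, age band and
#' disability type, with relative and geometric annual changes between the
#' first and last requested year appended per stratum. Values are carried
#' unrounded; rounding belongs to presentation.
#'
#' @param traj A trajectory.
#' @param years Calendar years to tabulate (changes compare first vs last).
#' @param bands Named list of age bands.
#' @param sexes Sex selections to include.
#' @param dtypes Disability-type selections (`"all"` and/or specific
#'   labels).
#' @return A data frame with columns `year`, `sex`, `age_band`, `dtype`,
#'   `value` (thousands) plus change rows carrying `measure`.
#' @export
disability_count_table <- function(traj, years = c(2015L, 2025L),
                                   bands = list("65+" = c(65, Inf),
                                                "65-84" = c(65, 84),
                                                "85+" = c(85, Inf)),
                                   sexes = c("all", "male", "female"),
                                   dtypes = "all") {
  rows <- list()
  for (sx in sexes) for (b in names(bands)) for (dt in dtypes) {
    vals <- vapply(years, function(y) {
      disability_count(traj, y, bands[[b]], sx, dt)
    }, numeric(1))
    for (k in seq_along(years)) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure = "count_thousands", year = years[k], sex = sx,
        age_band = b, dtype = dt, value = vals[k],
        stringsAsFactors = FALSE)
    }
    ny <- years[length(years)] - years[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "relative_change_pct", year = NA_integer_, sex = sx,
      age_band = b, dtype = dt,
      value = relative_change(vals[1L], vals[length(vals)]),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "annual_relative_change_pct", year = NA_integer_, sex = sx,
      age_band = b, dtype = dt,
      value = annual_relative_change(vals[1L], vals[length(vals)], ny),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Age-standardised prevalence summary table
#'
#' @inheritParams disability_count_table
#' @param std A [standard_population()].
#' @return Data frame with columns `year`, `sex`, `age_band`, `value`
#'   (percent).
#' @export
prevalence_table <- function(traj, std, years = c(2015L, 2025L),
                             bands = list("65+" = c(65, Inf),
                                          "75+" = c(75, Inf),
                                          "85+" = c(85, Inf)),
                             sexes = c("all", "male", "female")) {
  grid <- expand.grid(year = years, sex = sexes, age_band = names(bands),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(y, sx, b) {
    age_standardised_prevalence(traj, y, std, bands[[b]], sx)
  }, grid$year, grid$sex, grid$age_band)
  grid
}
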