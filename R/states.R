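#' The ten-state health state space
#'
#' The model tracks a population through eight alive states — every
#' combination of cardiovascular disease (CVD), cognitive impairment and
#' moderate-to-severe functional impairment (disability) — plus two absorbing
#' death states (CVD and non-CVD causes). Dementia is defined as the
#' coexistence of cognitive impairment and disability, so the two alive
#' states with both flags set are the dementia states.
#'
#' @return A data frame with one row per state and columns `code`, `alive`,
#'   `has_cvd`, `has_cognitive_impairment`, `has_disability`, `has_dementia`
#'   and `disability_type`. Row order is the canonical state order used by
#'   every matrix in the package.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  df <- data.frame(
    code = state_codes(),
    alive = c(rep(TRUE, 8L), FALSE, FALSE),
    has_cvd = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, NA, NA),
    has_cognitive_impairment =
      c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, NA, NA),
    has_disability =
      c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, NA, NA),
    stringsAsFactors = FALSE
  )
  # dementia = cognitive impairment together with ADL disability
  df$has_dementia <- df$has_cognitive_impairment & df$has_disability
  df$disability_type <- classify_disability(df$code)
  df
}

#' Canonical state codes
#'
#' Stable string identifiers used in every input and output file. Alive
#' states come first, the two absorbing death states last.
#'
#' @return Character vector of length 10.
#' @export
state_codes <- function() {
  c("FREE", "CVD", "CIND", "CVD_CIND",
    "DIS_OTHER", "DIS_CVD", "DIS_DEM", "DIS_CVD_DEM",
    "DEAD_CVD", "DEAD_NONCVD")
}

#' Codes of the eight alive states
#' @return Character vector of length 8.
#' @export
alive_states <- function() state_codes()[1:8]

#' Codes of the two absorbing death states
#' @return Character vector of length 2.
#' @export
death_states <- function() state_codes()[9:10]

#' Disability-type labels
#'
#' The four disabled states partition one-to-one onto four disability types;
#' all non-disabled (and dead) states map to `"NONE"`.
#'
#' @return Character vector of the five labels.
#' @export
disability_types <- function() {
  c("NONE", "CVD_RELATED", "DEMENTIA_RELATED",
    "CVD_AND_DEMENTIA_RELATED", "OTHER_RELATED")
}

#' Classify a state's disability type
#'
#' Maps each state to the aetiological class of its disability: CVD-related,
#' dementia-related, both, or other disease-related (disability not linked to
#' CVD or dementia). States without disability, and the death states, map to
#' `"NONE"`.
#'
#' @param state Character vector of state codes (see [state_codes()]).
#' @return Character vector of disability-type labels, same length as
#'   `state`.
#' @export
#' @examples
#' classify_disability(c("FREE", "DIS_CVD_DEM", "DIS_OTHER"))
classify_disability <- function(state) {
  map <- c(
    FREE = "NONE", CVD = "NONE", CIND = "NONE", CVD_CIND = "NONE",
    DIS_OTHER = "OTHER_RELATED",
    DIS_CVD = "CVD_RELATED",
    DIS_DEM = "DEMENTIA_RELATED",
    DIS_CVD_DEM = "CVD_AND_DEMENTIA_RELATED",
    DEAD_CVD = "NONE", DEAD_NONCVD = "NONE"
  )
  bad <- setdiff(unique(state), names(map))
  if (length(bad) > 0L) {
    stop("unknown state code(s): ", paste(bad, collapse = ", "),
         "; valid codes are: ", paste(state_codes(), collapse = ", "))
  }
  unname(map[state])
}

#' Transition legality mask
#'
#' A 10 x 10 logical matrix saying which annual state-to-state moves the
#' model permits. Two presets are shipped:
#'
#' * `"permissive"`: every alive-to-alive arc is allowed.
#' * `"progressive"` (default elsewhere in the package): additionally forbids
#'   remission arcs — established CVD is never lost, and the dementia states
#'   cannot lose cognitive impairment. Disability-only remission remains
#'   allowed (ADL limitation can be transient).
#'
#' Under every preset each alive state can move to both death states, the
#' death states are absorbing (self-transition only), and every state may
#' remain where it is.
#'
#' @param preset `"progressive"` or `"permissive"`.
#' @return Logical 10 x 10 matrix with state codes as dimnames, class
#'   `"transition_mask"`.
#' @export
#' @examples
#' m <- transition_mask("progressive")
#' m["CVD", "FREE"]   # FALSE: CVD is never lost
#' m["DIS_DEM", "CIND"] # TRUE: disability-only remission allowed
transition_mask <- function(preset = c("progressive", "permissive")) {
  preset <- match.arg(preset)
  st <- health_states()
  codes <- st$code
  allowed <- matrix(FALSE, 10L, 10L, dimnames = list(from = codes, to = codes))
  alive <- st$alive
  # alive states: all alive->alive arcs plus both death arcs
  allowed[alive, ] <- TRUE
  # death states absorbing
  for (d in death_states()) allowed[d, d] <- TRUE
  if (preset == "progressive") {
    for (i in which(alive)) {
      for (j in which(alive)) {
        loses_cvd <- st$has_cvd[i] && !st$has_cvd[j]
        dementia_loses_ci <- st$has_dementia[i] && !st$has_cognitive_impairment[j]
        if (loses_cvd || dementia_loses_ci) allowed[i, j] <- FALSE
      }
    }
    diag(allowed) <- TRUE
  }
  structure(allowed, class = c("transition_mask", "matrix", "array"),
            preset = preset)
}

#' Default transition mask for a scenario configuration
#'
#' @param config A scenario configuration list (see [scenario_config()]), or
#'   a single preset name.
#' @return A [transition_mask()].
#' @export
default_mask <- function(config = "progressive") {
  preset <- if (is.list(config)) config$mask_preset else config
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% c("progressive", "permissive")) {
    stop("unknown mask preset: ", deparse(preset),
         "; available presets are 'progressive' and 'permissive'")
  }
  transition_mask(preset)
}

#' @export
print.transition_mask <- function(x, ...) {
  cat("<transition_mask> preset:", attr(x, "preset"),
      "-", sum(x), "of 100 arcs allowed\n")
  print(unclass(x))
  invisible(x)
}

# Internal: index helpers against the canonical order
.state_index <- function(codes) {
  i <- match(codes, state_codes())
  if (anyNA(i)) {
    stop("unknown state code(s): ",
         paste(codes[is.na(i)], collapse = ", "))
  }
  i
}

#' Arc classes used by calendar trends
#'
#' Classifies every ordered state pair into the arc families that calendar
#' trends act on, derived from state attributes:
#'
#' * dementia incidence: alive non-dementia state to alive dementia state;
#' * CVD incidence: alive non-CVD state to alive CVD state;
#' * CVD mortality: alive state to `DEAD_CVD`;
#' * non-CVD mortality: alive state to `DEAD_NONCVD`.
#'
#' An arc can belong to both incidence families (for example `FREE ->
#' DIS_CVD_DEM` acquires CVD and dementia in the same cycle); trend scaling
#' then applies both factors multiplicatively.
#'
#' @return Named list of four logical 10 x 10 matrices.
#' @export
arc_classes <- function() {
  st <- health_states()
  alive <- st$alive
  dem <- !is.na(st$has_dementia) & st$has_dementia
  cvd <- !is.na(st$has_cvd) & st$has_cvd
  zero <- matrix(FALSE, 10L, 10L,
                 dimnames = list(from = st$code, to = st$code))
  dem_inc <- cvd_inc <- cvd_death <- noncvd_death <- zero
  dem_inc[alive & !dem, alive & dem] <- TRUE
  cvd_inc[alive & !cvd, alive & cvd] <- TRUE
  cvd_death[alive, "DEAD_CVD"] <- TRUE
  noncvd_death[alive, "DEAD_NONCVD"] <- TRUE
  list(
    dementia_incidence = dem_inc,
    cvd_incidence = cvd_inc,
    cvd_mortality = cvd_death,
    noncvd_mortality = noncvd_death
  )
}
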