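# Toy builders used across the suite. All fixtures are constructed in code.

# 10x10 matrix from a list of arcs c(from, to, p); the diagonal absorbs the
# remainder so every row is stochastic, death rows are identity.
toy_matrix <- function(arcs = list()) {
  codes <- state_codes()
  P <- matrix(0, 10L, 10L, dimnames = list(codes, codes))
  for (arc in arcs) {
    P[arc[[1]], arc[[2]]] <- as.numeric(arc[[3]])
  }
  for (i in seq_len(10L)) {
    P[i, i] <- 0
    P[i, i] <- 1 - sum(P[i, ])
  }
  P
}

# year-constant schedule replicating one matrix (or a function(age) -> matrix)
# over all ages, sexes and years
toy_schedule <- function(mat, ages = 60:65, years = 2006:2008) {
  na <- length(ages)
  base <- array(NA_real_, c(na, 2L, 10L, 10L))
  for (a in seq_len(na)) {
    M <- if (is.function(mat)) mat(ages[a]) else mat
    base[a, 1L, , ] <- M
    base[a, 2L, , ] <- M
  }
  constant_schedule(base, ages, years = years)
}

# population tensor with the given occupancy assignments
# (list of c(age, sex_index, state_code, count))
toy_population <- function(cells, year = 2006, ages = 60:65) {
  counts <- array(0, c(length(ages), 2L, 10L))
  for (cell in cells) {
    a <- match(as.integer(cell[[1]]), ages)
    counts[a, as.integer(cell[[2]]), .toy_state(cell[[3]])] <-
      as.numeric(cell[[4]])
  }
  population_tensor(counts, year, ages)
}

.toy_state <- function(code) match(code, state_codes())

# small synthetic spec for fast end-to-end tests: reduced age range with
# mortality rescaled so the hazard level at the new starting age matches the
# default curve at that age
small_spec <- function(age_min = 60L, ...) {
  shift <- age_min - 35L
  args <- list(...)
  if (!"gompertz_mortality" %in% names(args)) {
    args$gompertz_mortality <- list(
      noncvd = list(alpha = c(male = 5.2e-4, female = 3.6e-4) *
                      exp(0.092 * shift), beta = 0.092),
      cvd = list(alpha = c(male = 1.6e-4, female = 0.8e-4) *
                   exp(0.1 * shift), beta = 0.1)
    )
  }
  do.call(synthetic_spec, c(list(age_min = age_min), args))
}
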