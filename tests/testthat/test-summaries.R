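test_that("disability counts sum the matching states in thousands", {
  pop <- toy_population(list(
    list(70, 1, "DIS_OTHER", 500), list(90, 1, "DIS_CVD", 250),
    list(70, 1, "FREE", 4000), list(50, 2, "DIS_DEM", 800)),
    ages = 35:100)
  traj <- structure(list(years = 2006L, tensors = list(pop),
                         provenance = NULL), class = "trajectory")
  expect_equal(disability_count(traj, 2006, c(65, Inf)), 0.75)
  expect_equal(disability_count(traj, 2006, c(65, Inf), dtype = "CVD_RELATED"),
               0.25)
  expect_equal(disability_count(traj, 2006, c(35, Inf), "female"), 0.8)
  expect_equal(disability_count(traj, 2006, "65+", "male", "OTHER_RELATED"),
               0.5)
  # zero occupancy in disabled states
  expect_equal(disability_count(traj, 2006, c(95, 100)), 0)
  expect_error(disability_count(traj, 2006, c(200, 300)), "empty age band")
  expect_error(disability_count(traj, 2006, dtype = "BROKEN_LEG"),
               "unknown disability type")
})

test_that("counts are additive over age bands and disability types", {
  bundle <- generate_inputs(synthetic_spec())
  traj <- run_projection(bundle$initial, bundle$schedule, bundle$entrants,
                         2015)
  whole <- disability_count(traj, 2015, c(65, Inf))
  expect_equal(disability_count(traj, 2015, c(65, 84)) +
                 disability_count(traj, 2015, c(85, Inf)), whole)
  by_type <- vapply(setdiff(disability_types(), "NONE"), function(dt) {
    disability_count(traj, 2015, c(65, Inf), dtype = dt)
  }, numeric(1))
  expect_equal(sum(by_type), whole)
  by_sex <- disability_count(traj, 2015, c(65, Inf), "male") +
    disability_count(traj, 2015, c(65, Inf), "female")
  expect_equal(by_sex, whole)
})

test_that("direct standardisation matches hand computation and invariances", {
  # two ages, prevalence 10% and 30%, weights 1 and 3 -> 25%
  pop <- toy_population(list(
    list(70, 1, "DIS_OTHER", 10), list(70, 1, "FREE", 90),
    list(71, 1, "DIS_OTHER", 30), list(71, 1, "FREE", 70)),
    ages = 70:71)
  traj <- structure(list(years = 2006L, tensors = list(pop),
                         provenance = NULL), class = "trajectory")
  std <- standard_population(cbind(c(1, 3), c(0, 0)), 70:71)
  expect_equal(age_standardised_prevalence(traj, 2006, std, c(70, 71)), 25)
  # invariant to uniform scaling of the weights
  std10 <- standard_population(cbind(c(10, 30), c(0, 0)), 70:71)
  expect_equal(age_standardised_prevalence(traj, 2006, std10, c(70, 71)), 25)
  # constant age-specific prevalence p gives p for any weights
  pop2 <- toy_population(list(
    list(70, 1, "DIS_CVD", 20), list(70, 1, "FREE", 80),
    list(71, 1, "DIS_CVD", 2), list(71, 1, "CVD", 8)),
    ages = 70:71)
  traj2 <- structure(list(years = 2006L, tensors = list(pop2),
                          provenance = NULL), class = "trajectory")
  for (w in list(c(1, 1), c(5, 2), c(0.1, 9))) {
    stdw <- standard_population(cbind(w, c(0, 0)), 70:71)
    expect_equal(age_standardised_prevalence(traj2, 2006, stdw, c(70, 71)),
                 20)
  }
})

test_that("standardising with the population's own weights gives crude prevalence", {
  bundle <- generate_inputs(synthetic_spec())
  traj <- run_projection(bundle$initial, bundle$schedule, bundle$entrants,
                         2015)
  tn <- trajectory_year(traj, 2015)
  own <- standard_population(
    cbind(rowSums(tn$counts[, 1L, 1:8]), rowSums(tn$counts[, 2L, 1:8])),
    tn$ages)
  sel <- tn$ages >= 65
  crude <- 100 * sum(tn$counts[sel, , 5:8]) / sum(tn$counts[sel, , 1:8])
  expect_equal(age_standardised_prevalence(traj, 2015, own, c(65, Inf)),
               crude)
})

test_that("ages with zero alive but positive weight are excluded with a warning", {
  pop <- toy_population(list(list(70, 1, "DIS_OTHER", 10),
                             list(70, 1, "FREE", 90)), ages = 70:71)
  traj <- structure(list(years = 2006L, tensors = list(pop),
                         provenance = NULL), class = "trajectory")
  std <- standard_population(cbind(c(1, 1), c(1, 1)), 70:71)
  expect_warning(
    res <- age_standardised_prevalence(traj, 2006, std, c(70, 71), "male"),
    "zero alive")
  expect_equal(res, 10)
})

test_that("relative and annual change follow their definitions", {
  expect_equal(relative_change(2251, 2811), (2811 - 2251) / 2251 * 100)
  expect_equal(relative_change(100, 100), 0)
  expect_equal(relative_change(100, 50), -50)
  expect_error(relative_change(0, 5), "positive baseline")
  expect_equal(annual_relative_change(100, 100, 10), 0)
  expect_equal(annual_relative_change(100, 100 * 1.02^10, 10), 2)
  # compounding the annual rate recovers the total change
  v0 <- 2251; v1 <- 2811
  a <- annual_relative_change(v0, v1, 10)
  expect_equal(v0 * (1 + a / 100)^10, v1)
  expect_error(annual_relative_change(10, 20, 0), "years")
})

test_that("comparison reports flag exactly the offset keys", {
  model <- data.frame(year = c(2015, 2020, 2025), sex = "all",
                      value = c(10, 20, 30))
  expect_equal(max(abs(compare_series(model, model)$matched$abs_diff)), 0)
  ref <- model
  ref$value[2] <- 22
  rep_ <- compare_series(model, ref)
  flagged <- rep_$matched[rep_$matched$abs_diff != 0, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$year, 2020)
  expect_equal(flagged$rel_diff, -2 / 22)
  # key mismatch is listed, not fatal
  ref2 <- rbind(ref, data.frame(year = 2030, sex = "all", value = 40))
  rep2 <- compare_series(model[-1L, ], ref2)
  expect_equal(rep2$only_reference$year, c(2015, 2030))
  # rounding to whole thousands bounds the relative difference
  rounded <- model
  rounded$value <- round(model$value)
  rep3 <- compare_series(model, rounded)
  expect_true(all(abs(rep3$matched$abs_diff) <= 0.5))
})

test_that("summary tables carry consistent change rows", {
  bundle <- generate_inputs(small_spec(horizon = 2016L))
  traj <- run_projection(bundle$initial, bundle$schedule, bundle$entrants,
                         2016)
  tab <- disability_count_table(traj, years = c(2010L, 2016L))
  one <- tab[tab$sex == "all" & tab$age_band == "65+", ]
  v <- one$value[one$measure == "count_thousands"]
  rc <- one$value[one$measure == "relative_change_pct"]
  ac <- one$value[one$measure == "annual_relative_change_pct"]
  expect_equal(rc, relative_change(v[1], v[2]))
  expect_equal(v[1] * (1 + ac / 100)^6, v[2])
})
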