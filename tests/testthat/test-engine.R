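test_that("identity schedule shifts ages and pools the cap", {
  sched <- toy_schedule(toy_matrix(), ages = 98:100, years = 2006:2007)
  pop <- toy_population(list(
    list(98, 1, "FREE", 100), list(99, 1, "CVD", 50),
    list(100, 1, "CIND", 30), list(100, 2, "FREE", 10)),
    year = 2006, ages = 98:100)
  nxt <- step_year(pop, sched)
  expect_equal(nxt$year, 2007L)
  expect_equal(nxt$counts["99", "male", "FREE"], 100)
  expect_equal(nxt$counts["100", "male", "CVD"], 50)
  expect_equal(nxt$counts["100", "male", "CIND"], 30)  # pooled at the cap
  expect_equal(nxt$counts["100", "female", "FREE"], 10)
  expect_equal(sum(nxt$counts), sum(pop$counts))
})

test_that("certain death moves everyone to the death state at their age", {
  sched <- toy_schedule(toy_matrix(list(list("FREE", "DEAD_NONCVD", 1))),
                        ages = 60:65, years = 2006:2007)
  pop <- toy_population(list(list(64, 1, "FREE", 1)), ages = 60:65)
  nxt <- step_year(pop, sched)
  expect_equal(nxt$counts["64", "male", "DEAD_NONCVD"], 1)
  expect_equal(sum(nxt$counts[, , 1:8]), 0)
})

test_that("one step reproduces the hand-computed matrix-vector product", {
  # 2-age toy at the cap boundary with a mixed matrix
  M <- toy_matrix(list(
    list("FREE", "CVD", 0.2), list("FREE", "DEAD_CVD", 0.1),
    list("CVD", "DEAD_CVD", 0.3)))
  sched <- toy_schedule(M, ages = 99:100, years = 2006:2007)
  pop <- toy_population(list(
    list(99, 1, "FREE", 1000), list(100, 1, "FREE", 500),
    list(100, 1, "CVD", 200)), ages = 99:100)
  nxt <- step_year(pop, sched)
  # age 99 -> 100: FREE 1000*0.7, CVD 1000*0.2; deaths stay at 99
  # age 100 pool: FREE 500*0.7, CVD 500*0.2 + 200*0.7
  expect_equal(nxt$counts["100", "male", "FREE"], 1000 * 0.7 + 500 * 0.7)
  expect_equal(nxt$counts["100", "male", "CVD"],
               1000 * 0.2 + 500 * 0.2 + 200 * 0.7)
  expect_equal(nxt$counts["99", "male", "DEAD_CVD"], 1000 * 0.1)
  expect_equal(nxt$counts["100", "male", "DEAD_CVD"], 500 * 0.1 + 200 * 0.3)
})

test_that("entrants join the disease-free state at the youngest age", {
  sched <- toy_schedule(toy_matrix(), ages = 35:37, years = 2006:2010)
  ec <- entry_cohorts(2006:2011, cbind(rep(100, 6), rep(90, 6)))
  pop <- toy_population(list(list(36, 1, "FREE", 10)), ages = 35:37)
  nxt <- step_year(pop, sched, ec)
  expect_equal(nxt$counts["35", "male", "FREE"], 100)
  expect_equal(nxt$counts["35", "female", "FREE"], 90)
  expect_equal(nxt$counts["37", "male", "FREE"], 10)
  expect_error(step_year(pop, sched, entry_cohorts(2006, c(5, 5))),
               "no entry for year 2007")
  expect_error(entry_cohorts(2006:2007, matrix(-1, 2, 2)), "non-negative")
})

test_that("a trajectory equals the brute-force matrix chain", {
  mats <- list(
    toy_matrix(list(list("FREE", "CIND", 0.1), list("FREE", "DEAD_NONCVD", 0.05),
                    list("CIND", "DIS_DEM", 0.2))),
    toy_matrix(list(list("FREE", "CIND", 0.08), list("CIND", "DEAD_CVD", 0.1))),
    toy_matrix(list(list("DIS_DEM", "DEAD_NONCVD", 0.5))))
  # one age at the cap: ageing is a no-op, so the chain is a pure product
  na <- 1L
  p <- array(NA_real_, c(na, 2L, 3L, 10L, 10L))
  for (y in 1:3) for (s in 1:2) p[1L, s, y, , ] <- mats[[y]]
  sched <- transition_schedule(p, ages = 100L, years = 2006:2008)
  start <- c(1000, 0, 200, 0, 0, 0, 50, 0, 0, 0)
  counts <- array(0, c(1L, 2L, 10L))
  counts[1L, 1L, ] <- start
  pop <- population_tensor(counts, 2006, 100L)
  traj <- run_projection(pop, sched, NULL, 2009)
  v <- start
  for (y in 1:3) v <- as.vector(v %*% mats[[y]])
  expect_equal(as.vector(trajectory_year(traj, 2009)$counts[1L, 1L, ]), v)
  expect_equal(length(traj$years), 4L)
})

test_that("horizon at the initial year returns the initial tensor alone", {
  sched <- toy_schedule(toy_matrix(), ages = 60:61, years = 2006:2007)
  pop <- toy_population(list(list(60, 1, "FREE", 7)), ages = 60:61)
  traj <- run_projection(pop, sched, NULL, 2006)
  expect_equal(length(traj$years), 1L)
  expect_equal(trajectory_year(traj, 2006)$counts, pop$counts)
  expect_error(trajectory_year(traj, 2010), "does not cover")
})

test_that("identity projection conserves alive total plus entrants", {
  sched <- toy_schedule(toy_matrix(), ages = 35:45, years = 2006:2016)
  ec <- entry_cohorts(2006:2017, 50)
  pop <- toy_population(list(list(40, 1, "FREE", 1000)), ages = 35:45)
  traj <- run_projection(pop, sched, ec, 2016)
  final <- trajectory_year(traj, 2016)
  expect_equal(sum(final$counts[, , 1:8]), 1000 + 10 * 2 * 50)
})

test_that("conservation and non-negativity hold along a synthetic national run", {
  bundle <- generate_inputs(synthetic_spec())
  traj <- run_projection(bundle$initial, bundle$schedule, bundle$entrants,
                         2025)
  for (k in seq_along(traj$years)[-1L]) {
    t0 <- traj$tensors[[k - 1L]]; t1 <- traj$tensors[[k]]
    entr <- sum(bundle$entrants[as.character(traj$years[k]), ])
    expect_true(all(t1$counts >= 0))
    expect_lt(abs(sum(t1$counts) - sum(t0$counts) - entr),
              1e-6 * sum(t1$counts))
    # cumulative deaths never decrease, cell by cell
    expect_true(all(t1$counts[, , 9:10] - t0$counts[, , 9:10] > -1e-9))
  }
})

test_that("raising death probabilities cannot increase the alive total", {
  base_arcs <- list(list("FREE", "DEAD_NONCVD", 0.05),
                    list("FREE", "DEAD_CVD", 0.02),
                    list("FREE", "CIND", 0.1),
                    list("CIND", "DEAD_NONCVD", 0.08))
  raised <- list(list("FREE", "DEAD_NONCVD", 0.10),
                 list("FREE", "DEAD_CVD", 0.04),
                 list("FREE", "CIND", 0.1),
                 list("CIND", "DEAD_NONCVD", 0.16))
  pop <- toy_population(list(list(60, 1, "FREE", 1000),
                             list(62, 2, "FREE", 800)), ages = 60:65)
  alive <- function(arcs) {
    sched <- toy_schedule(toy_matrix(arcs), ages = 60:65, years = 2006:2012)
    traj <- run_projection(pop, sched, NULL, 2012)
    vapply(traj$years, function(y) {
      sum(trajectory_year(traj, y)$counts[, , 1:8])
    }, numeric(1))
  }
  expect_true(all(alive(raised) <= alive(base_arcs) + 1e-12))
})

test_that("missing schedule years and negative entrants are rejected", {
  sched <- toy_schedule(toy_matrix(), ages = 60:61, years = 2006:2007)
  pop <- toy_population(list(list(60, 1, "FREE", 1)), year = 2010,
                        ages = 60:61)
  expect_error(step_year(pop, sched), "no matrices for year 2010")
  pop2 <- toy_population(list(list(60, 1, "FREE", 1)), ages = 60:61)
  expect_error(step_year(pop2, sched, c(-5, 0)), "non-negative")
  expect_error(run_projection(pop2, sched, NULL, 2012),
               "does not cover")
})

test_that("expected sojourn matches closed-form geometric survival", {
  # constant 0.5 death probability from every alive state, one age at the
  # cap: expected alive years = sum over k >= 1 of 0.5^k = 1
  M <- toy_matrix(lapply(alive_states(), function(s) {
    list(s, "DEAD_NONCVD", 0.5)
  }))
  sched <- toy_schedule(M, ages = 100L, years = 2006L)
  expect_equal(expected_sojourn(alive_states(), 100, "male", sched), 1)
  # certain immediate death: zero years under start-of-interval counting
  M1 <- toy_matrix(lapply(alive_states(), function(s) {
    list(s, "DEAD_CVD", 1)
  }))
  sched1 <- toy_schedule(M1, ages = 65:100, years = 2006L)
  expect_equal(expected_sojourn(alive_states(), 65, "male", sched1), 0)
})

test_that("expected sojourn equals exhaustive path enumeration on a 2-age toy", {
  M99 <- toy_matrix(list(list("FREE", "CIND", 0.3),
                         list("FREE", "DEAD_NONCVD", 0.2),
                         list("CIND", "DEAD_NONCVD", 0.4)))
  M100 <- toy_matrix(lapply(alive_states(), function(s) {
    list(s, "DEAD_NONCVD", 1)
  }))
  p <- array(NA_real_, c(2L, 2L, 1L, 10L, 10L))
  for (s in 1:2) { p[1L, s, 1L, , ] <- M99; p[2L, s, 1L, , ] <- M100 }
  sched <- transition_schedule(p, ages = 99:100, years = 2006L)
  # paths from FREE at 99: after year 1 alive in {FREE 0.5, CIND 0.3} = 0.8
  # years; at age 100 certain death, so no further years
  expect_equal(expected_sojourn(alive_states(), 99, "male", sched), 0.8)
  # restricted to the CIND state only: 0.3 expected years
  expect_equal(expected_sojourn("CIND", 99, "male", sched), 0.3)
})

test_that("diverging sojourn (no mortality at the cap) is an error", {
  sched <- toy_schedule(toy_matrix(), ages = 100L, years = 2006L)
  expect_error(expected_sojourn(alive_states(), 100, "male", sched),
               "diverges")
})

test_that("trajectories round-trip through the long-table export", {
  bundle <- generate_inputs(small_spec(horizon = 2010L))
  traj <- run_projection(bundle$initial, bundle$schedule, bundle$entrants,
                         2010, provenance = list(run = "roundtrip-test"))
  tmp <- withr::local_tempfile(fileext = ".csv.gz")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$years, traj$years)
  for (y in traj$years) {
    expect_equal(trajectory_year(back, y)$counts,
                 trajectory_year(traj, y)$counts, tolerance = 1e-11)
  }
})
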