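test_that("period mortality is recovered from trajectory death increments", {
  # identity schedule: nobody dies
  sched <- toy_schedule(toy_matrix(), ages = 60:62, years = 2006:2007)
  pop <- toy_population(list(list(60, 1, "FREE", 10),
                             list(61, 1, "CVD", 5)), ages = 60:62)
  traj <- run_projection(pop, sched, NULL, 2007)
  expect_equal(unname(mortality_from_trajectory(traj, 2006)), c(0, 0, 0))

  # state-independent death probability 0.5 at every age
  M <- toy_matrix(lapply(alive_states(), function(s) {
    list(s, "DEAD_NONCVD", 0.5)
  }))
  sched2 <- toy_schedule(M, ages = 60:62, years = 2006:2007)
  pop2 <- toy_population(list(list(60, 1, "FREE", 100),
                              list(61, 2, "DIS_DEM", 40)), ages = 60:62)
  traj2 <- run_projection(pop2, sched2, NULL, 2007)
  q <- mortality_from_trajectory(traj2, 2006)
  expect_equal(unname(q[c("60", "61")]), c(0.5, 0.5))
})

test_that("an age-graded death schedule is recovered exactly", {
  # state-independent but age-specific death probability: q_a must equal
  # the schedule's total death-arc probability at every age
  p_death <- function(age) 0.02 * exp(0.08 * (age - 60))
  mat_at <- function(age) {
    toy_matrix(c(
      lapply(alive_states(), function(s) list(s, "DEAD_CVD",
                                              0.3 * p_death(age))),
      lapply(alive_states(), function(s) list(s, "DEAD_NONCVD",
                                              0.7 * p_death(age)))))
  }
  sched <- toy_schedule(mat_at, ages = 60:80, years = 2006:2007)
  cells <- lapply(60:80, function(a) list(a, 1, "FREE", 100))
  cells <- c(cells, lapply(60:80, function(a) list(a, 2, "DIS_CVD", 50)))
  pop <- toy_population(cells, ages = 60:80)
  traj <- run_projection(pop, sched, NULL, 2007)
  q <- mortality_from_trajectory(traj, 2006)
  expect_equal(unname(q), p_death(60:80), tolerance = 1e-12)
})

test_that("life tables reproduce the hand-computed 3-age oracle", {
  q <- c(0.1, 0.2, 1 - exp(-1))  # terminal central death rate m = 1
  lt <- build_life_table(q, ages = 98:100, radix = 1e5)
  expect_equal(lt$lx, c(1, 0.9, 0.72) * 1e5)
  expect_equal(lt$Lx, c(0.95, 0.81, 0.72) * 1e5)
  expect_equal(lt$Tx, c(2.48, 1.53, 0.72) * 1e5)
  expect_equal(lt$ex, c(2.48, 1.53 / 0.9, 1))
})

test_that("life-table conventions at the boundaries", {
  # no mortality below the cap: e_65 is 35 years plus the terminal tail
  q <- c(rep(0, 35), 0.5)
  lt <- build_life_table(q, ages = 65:100)
  expect_equal(lt$ex[1], 35 + 1 / (-log(0.5)))
  # certain death at the starting age: half a year under a_x = 0.5
  q1 <- c(1, rep(0.2, 35))
  lt1 <- build_life_table(q1, ages = 65:100)
  expect_equal(lt1$ex[1], 0.5)
  # monotone survivorship, q range checks, terminal q = 0 rejected
  expect_true(all(diff(lt$lx) <= 0))
  expect_error(build_life_table(c(0.1, 1.2), ages = 99:100), "\\[0, 1\\]")
  expect_error(build_life_table(c(0.1, 0), ages = 99:100), "unbounded")
})

test_that("Sullivan decomposition is exactly additive and handles extremes", {
  q <- c(0.05, 0.1, 0.3, 0.8, 1 - exp(-1.2))
  lt <- build_life_table(q, ages = 96:100)
  prev0 <- stats::setNames(rep(0, 5), 96:100)
  prev1 <- stats::setNames(rep(1, 5), 96:100)
  r0 <- sullivan(lt, prev0, 96)
  expect_equal(r0$disability_free, r0$total)
  expect_equal(r0$disabled, 0)
  r1 <- sullivan(lt, prev1, 96)
  expect_equal(r1$disabled, r1$total)
  expect_equal(r1$proportion_disabled, 100)
  # constant prevalence factors out: proportion = pi for any life table
  prev25 <- stats::setNames(rep(0.25, 5), 96:100)
  r25 <- sullivan(lt, prev25, 96)
  expect_equal(r25$proportion_disabled, 25)
  expect_equal(r25$disability_free + r25$disabled, r25$total)
  # missing prevalence at a contributing age is an error
  expect_error(sullivan(lt, prev25[-2], 96), "missing at contributing")
})

test_that("decomposition of change differences all components", {
  r0 <- list(at_age = 65, total = 20.1, disability_free = 15.4,
             disabled = 4.7, proportion_disabled = 100 * 4.7 / 20.1)
  expect_equal(decompose_change(r0, r0),
               list(total = 0, disability_free = 0, disabled = 0,
                    proportion_disabled = 0))
  r1 <- list(at_age = 65, total = 21.8, disability_free = 16.4,
             disabled = 5.4, proportion_disabled = 100 * 5.4 / 21.8)
  d <- decompose_change(r0, r1)
  expect_equal(d$total, d$disability_free + d$disabled)
  r2 <- r1; r2$at_age <- 70
  expect_error(decompose_change(r0, r2), "different ages")
})

test_that("Sullivan agrees with the absorbing-chain sojourn oracle", {
  # state-independent mortality and a single simulated cohort make the
  # life-table route and the Markov-chain route describe the same process
  p_death <- function(age) pmin(0.01 * exp(0.09 * (age - 60)), 0.9)
  mat_at <- function(age) {
    toy_matrix(c(list(list("FREE", "DIS_OTHER", 0.05)),
                 lapply(alive_states(), function(s) {
                   list(s, "DEAD_NONCVD", p_death(age))
                 })))
  }
  ages <- 60:100
  sched <- toy_schedule(mat_at, ages = ages, years = 2006L)
  sojourn_alive <- expected_sojourn(alive_states(), 60, "male", sched)
  sojourn_dis <- expected_sojourn(c("DIS_OTHER", "DIS_CVD", "DIS_DEM",
                                    "DIS_CVD_DEM"), 60, "male", sched)
  # simulate the cohort to read period mortality and prevalence
  pop <- toy_population(list(list(60, 1, "FREE", 1e5)), ages = ages)
  years <- 2006L + seq_len(length(ages) + 1L) - 1L
  sched_long <- toy_schedule(mat_at, ages = ages,
                             years = c(years, max(years) + 1L))
  traj <- run_projection(pop, sched_long, NULL, max(years) + 1L)
  # cohort mortality by age = period mortality read along the diagonal;
  # with state-independent death probability both equal p_death(age)
  q <- stats::setNames(p_death(ages), ages)
  q[length(q)] <- 1 - (1 - p_death(100))  # cap row keeps its own q
  lt <- build_life_table(q, ages = ages)
  # prevalence by age along the cohort diagonal
  pi_a <- vapply(seq_along(ages), function(k) {
    tn <- trajectory_year(traj, 2006L + k - 1L)
    alive <- sum(tn$counts[k, 1L, 1:8])
    if (alive == 0) 0 else sum(tn$counts[k, 1L, 5:8]) / alive
  }, numeric(1))
  # the cap age keeps a mixed population; use its asymptotic mix instead
  names(pi_a) <- ages
  s <- sullivan(lt, pi_a, 60)
  # a_x = 0.5 discretisation: the life-table expectancy counts half the
  # death year, the start-of-interval chain does not
  expect_lt(abs(s$total - (sojourn_alive + 0.5)), 0.5)
  expect_lt(abs(s$disabled - sojourn_dis) / max(sojourn_dis, 1), 0.35)
})
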