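test_that("cumulative risks annualize by both conventions", {
  expect_equal(annualize_cumulative_risk(0.77, 10, "uniform"), 0.077)
  expect_equal(annualize_cumulative_risk(0, 5, "uniform"), 0)
  expect_equal(annualize_cumulative_risk(0, 5, "geometric"), 0)
  expect_equal(annualize_cumulative_risk(0.042, 10, "geometric"),
               1 - (1 - 0.042)^0.1)
  expect_equal(annualize_cumulative_risk(0.042, 10, "geometric"), 0.00428,
               tolerance = 1e-3)
  expect_error(annualize_cumulative_risk(1, 10), "cumulative_p")
  # geometric conversion is exact: compounding the annual risk recovers the
  # cumulative figure
  ann <- annualize_cumulative_risk(0.6, 7, "geometric")
  expect_equal(1 - (1 - ann)^7, 0.6)
})

test_that("cohort projection reproduces the published yearly survivor counts", {
  traj <- project_cohort(250, 0.077, 10)
  expect_equal(traj$patients, table4_patients())
  expect_equal(traj$alive, 250 * 0.923^(1:10))
  expect_equal(project_cohort(250, 0, 10)$patients, rep(250, 10))
  expect_equal(project_cohort(0, 0.077, 10)$alive, rep(0, 10))
  expect_error(project_cohort(250, 1, 10), "annual_death")
})

test_that("a Markov cycle conserves the cohort and keeps dead absorbing", {
  s0 <- c(without_hl = 100, with_hl = 0, dead = 0)
  expect_equal(markov_step(s0, 0, 0), s0)
  s1 <- markov_step(s0, 0.077, 0.00428)
  expect_equal(unname(s1[["without_hl"]] + s1[["with_hl"]]), 92.3)
  expect_equal(unname(s1[["with_hl"]]), 92.3 * 0.00428)
  expect_equal(sum(s1), 100)
  # near-certain death empties the alive states
  s2 <- markov_step(s0, 1 - 1e-9, 0.1)
  expect_lt(s2[["without_hl"]] + s2[["with_hl"]], 1e-6)
  expect_error(markov_step(c(without_hl = -1, with_hl = 0, dead = 0), 0.1, 0.1),
               "negative")
  expect_error(markov_step(c(a = 1), 0.1, 0.1), "state")
})

test_that("multi-cycle trajectories conserve state counts exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n0 <- sample(50:2000, 1)
    death <- runif(1, 0, 0.5)
    hl <- runif(1, 0, 0.1)
    traj <- markov_trajectory(n0, death, hl, years = 10)
    totals <- traj$without_hl + traj$with_hl + traj$dead
    expect_true(all(abs(totals - n0) < 1e-9))
    expect_true(all(diff(traj$alive) <= 0))
    expect_true(all(diff(traj$dead) >= 0))
  }
})

test_that("discounting uses the year-1-undiscounted convention", {
  expect_equal(discount_factor(0.0679, 1), 1)
  expect_equal(discount_factor(0, 7), 1)
  expect_equal(discount_factor(0.0679, 2), 1 / 1.0679)
  expect_equal(discount_factor(0.0679, 2), 0.9364, tolerance = 1e-4)
  expect_error(discount_factor(-0.1, 1), "rate")
  expect_error(discount_factor(0.05, 0), "year")
})

test_that("ten-year savings totals and per-patient divisions are consistent", {
  traj <- project_cohort(250, 0.077, 10)
  # aggregate mode: total equals the sum of its inputs exactly
  ann <- table4_annual()
  tab <- ten_year_savings(traj, annual_saving = ann)
  expect_identical(sum(tab$annual_saving), sum(ann))
  expect_equal(round(tab$per_patient_saving[3], 2), 12.44)
  expect_error(ten_year_savings(traj, annual_saving = ann[1:5]), "length")

  # model mode: zero schedule gives zero savings; a constant schedule gives
  # non-increasing discounted savings
  expect_equal(sum(ten_year_savings(traj, schedule = rep(0, 10),
                                    incidence_delta = 0.1)$annual_saving), 0)
  tabm <- ten_year_savings(traj, schedule = rep(73.81, 10),
                           incidence_delta = 0.11, rate = 0.0679)
  expect_true(all(diff(tabm$annual_saving) < 0))
  expect_equal(tabm$annual_saving[1], 0.11 * 250 * 0.923 * 73.81)
  expect_error(ten_year_savings(traj, schedule = rep(1, 3),
                                incidence_delta = 0.1), "length")
})

test_that("savings components sum to the grand total", {
  comp <- savings_components(10540.71, 2537.02)
  expect_equal(comp$total, 13077.73)
  expect_lt(abs(comp$device_total + comp$support_total - comp$total), 0.01)
  expect_equal(comp$device_share, 10540.71 / 13077.73)
  expect_equal(savings_components(0, 0)$total, 0)
  expect_error(savings_components(-1, 0), "non-negative")
})
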