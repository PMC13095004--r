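probs_at_medians <- function() {
  arm_probabilities(p1 = 0.42, p2 = 0.03, p3 = 0.02, p4 = 0.35,
                    p5 = 0.18, p6 = 0.09)
}

test_that("genotyping unit cost honours the lookup, then the parametric model", {
  expect_equal(genotyping_unit_cost(3), 26.27)
  expect_equal(genotyping_unit_cost(5), 17.12)
  mod <- batch_cost_model(reagent_usd_per_test = 0, labor_usd_per_batch = 0)
  expect_equal(genotyping_unit_cost(4, lookup = NULL, model = mod), 0)
  expect_error(genotyping_unit_cost(7), "parametric model")
  expect_error(genotyping_unit_cost(0), "batch_size")
  # parametric cost is non-increasing in batch size
  mod <- batch_cost_model(reagent_usd_per_test = 5, control_tests_per_batch = 2,
                          loss_fraction = 0.10, labor_usd_per_batch = 20)
  costs <- vapply(1:10, genotyping_unit_cost, numeric(1),
                  lookup = NULL, model = mod)
  expect_true(all(diff(costs) <= 0))
})

test_that("conventional-arm expected cost follows the decision tree", {
  probs <- probs_at_medians()
  ci0 <- cost_inputs(first_year_oto_usd = 0)
  expect_equal(expected_cost_conventional(probs, ci0), 307.02)
  probs0 <- arm_probabilities(0.42, 0.03, 0.02, 0, 0.18, 0.09)
  ciH <- cost_inputs(first_year_oto_usd = 500)
  expect_equal(expected_cost_conventional(probs0, ciH), 307.02)
  H <- 123.45
  ci <- cost_inputs(first_year_oto_usd = H)
  expect_equal(expected_cost_conventional(probs, ci),
               307.02 + 0.97 * 0.35 * H)
  expect_error(expected_cost_conventional(probs, cost_inputs()),
               "first_year_oto_usd")
})

test_that("genotype-arm expected cost follows the decision tree", {
  probs <- probs_at_medians()
  H <- 200
  ci <- cost_inputs(first_year_oto_usd = H)
  got <- expected_cost_genotyped(probs, ci, batch_size = 3, cohort_n = 500)
  want <- 26.27 + 7668 / 500 + 0.42 * 270.29 + 0.58 * 307.02 +
    (0.58 * 0.97 * 0.18 + 0.42 * 0.98 * 0.09) * H
  expect_equal(got, want)

  # degenerate tree: no high-risk patients, no testing costs -> conventional
  # arm with p5 in place of p4
  probs0 <- arm_probabilities(0, 0.03, 0.02, 0.35, 0.18, 0.09)
  ci0 <- cost_inputs(genotyping_unit_usd_by_batch = c("3" = 0),
                     equipment_usd = 0, annual_amortization_usd = 0,
                     first_year_oto_usd = H)
  probs_swap <- arm_probabilities(0, 0.03, 0.02, 0.18, 0.18, 0.09)
  expect_equal(expected_cost_genotyped(probs0, ci0, 3, 100),
               expected_cost_conventional(probs_swap, ci0))
  # amortization share vanishes for very large cohorts
  ci_amort <- cost_inputs(genotyping_unit_usd_by_batch = c("3" = 0),
                          cddp_course_usd = 0, docetaxel_course_usd = 0,
                          first_year_oto_usd = 0)
  expect_lt(expected_cost_genotyped(probs, ci_amort, 3, 1e9), 1e-4)
  expect_error(expected_cost_genotyped(probs, ci, 3, 0), "cohort_n")
})

test_that("calibration from the 500-patient row reproduces the difference column", {
  expect_equal(calibrate_variable_saving(14.01, 7668, 500), 29.346)
  expect_equal(calibrate_variable_saving(0, 0, 100), 0)
  expect_equal(calibrate_variable_saving(23.16, 7668, 500), 38.496)
  k <- calibrate_variable_saving(14.01, 7668, 500)
  expect_equal(per_patient_difference(k, 7668, 25), -277.374,
               tolerance = 1e-10)
  expect_equal(per_patient_difference(k, 7668, 250), -1.326,
               tolerance = 1e-10)
  expect_equal(per_patient_difference(5, 0, 10), 5)
  expect_equal(per_patient_difference(5, 0, 10000), 5)
})

test_that("calibration from any published row recovers every other difference", {
  grid <- seq(25L, 500L, by = 25L)
  diffs <- table3_differences()
  for (i in seq_along(grid)) {
    k <- calibrate_variable_saving(diffs[i], 7668, grid[i])
    pred <- per_patient_difference(k, 7668, grid)
    expect_lt(max(abs(pred - diffs)), 0.01,
              label = sprintf("calibrated from cohort %d", grid[i]))
  }
})

test_that("break-even search returns the smallest profitable grid point", {
  expect_identical(break_even_cohort(29.346, 7668, 25), 275L)
  expect_identical(break_even_cohort(38.496, 7668, 25), 200L)
  expect_identical(break_even_cohort(10, 0, 25), 25L)
  expect_warning(n <- break_even_cohort(0, 7668, 25), "no break-even")
  expect_true(is.na(n))
  expect_warning(break_even_cohort(-5, 7668, 25), "no break-even")
  # definition: diff(N*) > 0 >= diff(N* - step)
  for (k in c(5, 29.346, 100)) {
    n_star <- break_even_cohort(k, 7668, 25)
    expect_gt(per_patient_difference(k, 7668, n_star), 0)
    if (n_star > 25)
      expect_lte(per_patient_difference(k, 7668, n_star - 25L), 0)
  }
})

test_that("batch effect shifts the difference by the unit-cost gap", {
  expect_equal(batch_effect(14.01, 26.27, 17.12), 23.16)
  expect_equal(batch_effect(14.01, 20, 20), 14.01)
  expect_equal(batch_effect(-277.37, 26.27, 17.12), -268.22)
  expect_error(batch_effect(1, -1, 0), "non-negative")
})

test_that("cohort cost table has the published shape and monotonicity", {
  probs <- probs_at_medians()
  ci <- cost_inputs(first_year_oto_usd = 180)
  tab <- cohort_cost_table(probs, ci)
  expect_equal(nrow(tab), 20L)
  expect_true(all(diff(tab$difference) > 0))
  expect_equal(unique(tab$cost_conventional),
               expected_cost_conventional(probs, ci))
  # genotype-arm cost falls strictly as the batch unit cost falls
  tab5 <- cohort_cost_table(probs, ci, batch_size = 5)
  expect_true(all(tab5$cost_genotyped < tab$cost_genotyped))
  expect_equal(tab5$cost_conventional, tab$cost_conventional)
  expect_error(cohort_cost_table(probs, ci, cohort_grid = integer(0)),
               "empty")
})
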