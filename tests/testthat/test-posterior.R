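test_that("conjugate posterior adds pseudo-counts", {
  post <- conjugate_posterior(beta_prior(58, 91), binom_obs(26, 63))
  expect_equal(c(post$alpha, post$beta), c(84, 154))
  post <- conjugate_posterior(beta_prior(10, 91), binom_obs(1, 16))
  expect_equal(c(post$alpha, post$beta), c(11, 107))
  post <- conjugate_posterior(beta_prior(1, 1), binom_obs(0, 0))
  expect_equal(c(post$alpha, post$beta), c(1, 1))
  expect_error(beta_prior(0, 1), "alpha")
  expect_error(beta_prior(1, -2), "beta")
  expect_error(binom_obs(-1, 5), "events")
  expect_error(binom_obs(1.5, 5), "events")
})

test_that("beta quantiles invert the incomplete beta function", {
  expect_equal(beta_quantile(beta_prior(1, 1), 0.5), 0.5)
  # frozen from numeric inversion; round to the printed two-decimal medians
  expect_equal(beta_quantile(beta_prior(84, 154), 0.5), 0.3525286,
               tolerance = 1e-6)
  expect_equal(beta_quantile(beta_prior(11, 107), 0.5), 0.0909239,
               tolerance = 1e-5)
  expect_equal(round(beta_quantile(beta_prior(84, 154), 0.5), 2), 0.35)
  expect_equal(round(beta_quantile(beta_prior(11, 107), 0.5), 2), 0.09)
  expect_error(beta_quantile(beta_prior(1, 1), 0), "q")
  expect_error(beta_quantile(beta_prior(1, 1), 1), "q")
})

test_that("sampler is deterministic per seed and stays inside (0,1)", {
  rec <- evidence_record("P4", binom_obs(26, 63), beta_prior(58, 91))
  cfg <- mcmc_config(seed = 7L)
  s1 <- mh_sample(rec, cfg)
  s2 <- mh_sample(rec, cfg)
  expect_identical(s1$values, s2$values)
  expect_length(s1$values, cfg$iterations - cfg$burn_in)
  expect_true(all(s1$values > 0 & s1$values < 1))
  expect_gt(s1$acceptance_rate, 0.1)
  expect_lt(s1$acceptance_rate, 0.9)
  s3 <- mh_sample(rec, mcmc_config(seed = 8L))
  expect_false(identical(s1$values, s3$values))
  expect_error(mcmc_config(proposal_sd = 0), "proposal_sd")
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "burn_in")
})

test_that("sampler medians agree with the conjugate oracle on every evidence row", {
  for (row in table2_rows()) {
    rec <- row_record(row)
    oracle <- beta_quantile(conjugate_posterior(rec$prior, rec$obs), 0.5)
    for (seed in 1:10) {
      s <- mh_sample(rec, mcmc_config(seed = seed))
      expect_lt(abs(median(s$values) - oracle), 0.005,
                label = sprintf("%s seed %d |MH median - oracle|",
                                row$label, seed))
    }
  }
})

test_that("sampler distribution matches i.i.d. conjugate draws (KS < 0.05)", {
  set.seed(99)
  for (row in table2_rows()) {
    rec <- row_record(row)
    post <- conjugate_posterior(rec$prior, rec$obs)
    s <- mh_sample(rec, mcmc_config(seed = 3L))
    ref <- rbeta(10000, post$alpha, post$beta)
    ks <- suppressWarnings(ks.test(s$values, ref))$statistic
    expect_lt(unname(ks), 0.05, label = paste(row$label, "KS distance"))
  }
})

test_that("sample summaries give median and equal-tailed 95% interval", {
  sm <- summarize_samples(rep(0.3, 100))
  expect_equal(c(sm$median, sm$ci_low, sm$ci_high), c(0.3, 0.3, 0.3))
  set.seed(11)
  sm <- summarize_samples(rbeta(50000, 84, 154))
  expect_equal(sm$median, beta_quantile(beta_prior(84, 154), 0.5),
               tolerance = 0.01)
  expect_equal(round(sm$median, 2), 0.35)
  sm <- summarize_samples(rbeta(50000, 11, 53))
  expect_equal(round(sm$median, 2), 0.17)
  expect_true(sm$ci_low <= sm$median && sm$median <= sm$ci_high)
  expect_error(summarize_samples(numeric(0)), "empty")
})

test_that("flat-data posterior with uniform prior centres at one half", {
  rec <- evidence_record("flat", binom_obs(0, 0), beta_prior(1, 1))
  s <- mh_sample(rec, mcmc_config(seed = 5L))
  # the posterior is uniform; allow Monte Carlo error on the sample median
  expect_lt(abs(median(s$values) - 0.5), 0.05)
})

test_that("diagnostics report acceptance, autocorrelation and ESS", {
  rec <- evidence_record("P4", binom_obs(26, 63), beta_prior(58, 91))
  s <- mh_sample(rec, mcmc_config(seed = 1L))
  d <- mcmc_diagnostics(s)
  expect_true(d$acceptance_rate >= 0 && d$acceptance_rate <= 1)
  expect_lte(d$ess, d$n)
  expect_gt(d$ess, 500)
  expect_false(d$degenerate)
  expect_s3_class(as.data.frame(d), "data.frame")

  # i.i.d. pseudo-chain: negligible lag-1 autocorrelation, ESS near n
  set.seed(2)
  iid <- structure(list(values = rbeta(10000, 84, 154),
                        acceptance_rate = 1, label = "iid"),
                   class = "prob_samples")
  di <- mcmc_diagnostics(iid)
  expect_lt(abs(di$autocorrelation[["lag1"]]), 0.05)

  # a stuck chain is flagged degenerate
  stuck <- structure(list(values = rep(0.3, 1000), acceptance_rate = 0,
                          label = "stuck"),
                     class = "prob_samples")
  ds <- mcmc_diagnostics(stuck)
  expect_true(ds$degenerate)
  expect_identical(ds$acceptance_rate, 0)
  expect_true(is.na(ds$ess))
})

test_that("posterior table covers all records with unique labels", {
  rows <- table2_rows()
  tab <- posterior_table(lapply(rows, row_record), mcmc_config(seed = 2L))
  expect_equal(nrow(tab), length(rows))
  expect_equal(tab$label, vapply(rows, `[[`, "", "label"))
  expect_true(all(abs(tab$median - tab$conjugate_median) < 0.005))
  dup <- lapply(rows[c(1, 1)], row_record)
  expect_error(posterior_table(dup, mcmc_config()), "unique")
})
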