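# Scenario generation: the published study scenario (all printed model
# inputs), randomized scenarios for property testing, and synthetic
# binomial trial counts with the generating process the Bernoulli model
# assumes.

#' Simulate binomial trial counts
#'
#' Draws `events ~ Binomial(n, true_p)` — the generating process the
#' Bayesian Bernoulli model assumes for every observed-data row — so that
#' synthetic records are exchangeable with published ones in every
#' downstream operation.
#'
#' @param true_p True event probability, strictly inside (0, 1).
#' @param n Number of trials.
#' @param seed Integer seed; counts are identical on repeat for a fixed
#'   seed.
#' @return A [binom_obs()] with `events + non_events == n`.
#' @export
simulate_trial_counts <- function(true_p, n, seed = 1L) {
  if (!is.numeric(true_p) || true_p <= 0 || true_p >= 1)
    stop("'true_p' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(as.integer(seed))
  k <- stats::rbinom(1L, size = as.integer(n), prob = true_p)
  binom_obs(k, n - k)
}

#' The published study scenario
#'
#' The fully populated configuration encoding every printed model input:
#' the six evidence records (P5 in its informative-prior variant, with the
#' non-informative variant alongside), all summary cost inputs, the 6.79%
#' discount rate, the 250-patient ten-year Markov settings, and the
#' published first-year and ten-year reference figures used for
#' calibration and aggregate-mode totals.
#'
#' The first-year ototoxicity management cost is not among the printed
#' summary inputs; the default here is backed out of the published
#' conventional-arm median cost at the conjugate posterior medians
#' (`H = (conv - cddp) / ((1-P2) P4)`), as documented in the methods
#' vignette.
#'
#' @param seed Scenario seed driving all per-record sub-seeds.
#' @param p5_variant Which P5 prior the decision tree uses:
#'   `"noninformative"` (default, the variant preferred for the cost
#'   simulations) or `"informative"`.
#' @return An object of class `scenario_config`.
#' @export
study_scenario <- function(seed = 1L,
                           p5_variant = c("noninformative", "informative")) {
  p5_variant <- match.arg(p5_variant)
  evidence <- list(
    evidence_record("P1", binom_obs(49, 40), beta_prior(178, 114)),
    evidence_record("P2", binom_obs(3, 89), beta_prior(8, 166)),
    evidence_record("P3", binom_obs(2, 89), beta_prior(4, 176)),
    evidence_record("P4", binom_obs(26, 63), beta_prior(58, 91)),
    if (p5_variant == "informative")
      evidence_record("P5", binom_obs(7, 33), beta_prior(4, 20))
    else
      evidence_record("P5", binom_obs(7, 33), noninformative_prior()),
    evidence_record("P6", binom_obs(1, 16), beta_prior(10, 91))
  )
  p5_alternative <- if (p5_variant == "informative")
    evidence_record("P5", binom_obs(7, 33), noninformative_prior())
  else
    evidence_record("P5", binom_obs(7, 33), beta_prior(4, 20))

  costs <- cost_inputs() # published summary inputs as defaults
  # back out the first-year ototoxicity management cost from the published
  # conventional-arm median at the conjugate medians of P2 and P4
  conv_median <- 368.19
  med <- function(rec) beta_quantile(conjugate_posterior(rec$prior, rec$obs), 0.5)
  p2_med <- med(evidence[[2]])
  p4_med <- med(evidence[[4]])
  costs$first_year_oto_usd <-
    (conv_median - costs$cddp_course_usd) / ((1 - p2_med) * p4_med)

  structure(list(
    seed = as.integer(seed),
    evidence = evidence,
    p5_variant = p5_variant,
    p5_alternative = p5_alternative,
    costs = costs,
    mcmc = mcmc_config(seed = as.integer(seed)),
    scenario = list(cohort_n = 250L, batch_size = 3L,
                    grid = seq(25L, 500L, by = 25L)),
    markov = list(n0 = 250L, horizon_years = 10L,
                  death_cumulative = 0.77,
                  death_annualization = "uniform",
                  hearingloss_cumulative = 0.042,
                  hearingloss_annualization = "geometric",
                  discount_rate = 0.0679),
    published = list(
      conventional_median = conv_median,
      diff_at_ref = 14.01, ref_n = 500L,
      diff_five_sample = 23.16,
      annual_reductions = c(442.93, 370.85, 2444.75, 2104.16, 1811.01,
                            1558.71, 1341.55, 1154.65, 993.79, 855.34),
      device_total = 10540.71,
      support_total = 2537.02
    )
  ), class = "scenario_config")
}

#' Random scenario for property testing
#'
#' Draws probabilities, costs and cohort sizes from wide ranges bracketing
#' the study values (probabilities in \[0.01, 0.8\], costs in \[0, 1000\],
#' cohorts in \[25, 2000\]) to fuzz-test model invariants across the
#' parameter space. Every generated scenario passes [validate_scenario()].
#'
#' @param seed Integer seed.
#' @return A `scenario_config`.
#' @export
random_scenario <- function(seed = 1L) {
  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rp <- function() stats::runif(1, 0.01, 0.8)
  rc <- function() stats::runif(1, 0, 1000)
  evidence <- lapply(paste0("P", 1:6), function(lab) {
    n <- sample(20:300, 1L)
    k <- stats::rbinom(1L, n, rp())
    evidence_record(lab, binom_obs(k, n - k),
                    beta_prior(stats::runif(1, 0.5, 200),
                               stats::runif(1, 0.5, 200)))
  })
  equip <- stats::runif(1, 0, 50000)
  amort_rate <- stats::runif(1, 0.05, 0.5)
  unit3 <- rc(); unit5 <- stats::runif(1, 0, unit3)
  costs <- cost_inputs(
    cddp_course_usd = rc(), docetaxel_course_usd = rc(),
    genotyping_unit_usd_by_batch = c("3" = unit3, "5" = unit5),
    equipment_usd = equip, amortization_rate = amort_rate,
    hearing_annual_usd = rc(),
    first_year_oto_usd = rc(),
    discount_rate = stats::runif(1, 0, 0.15))
  structure(list(
    seed = as.integer(seed),
    evidence = evidence,
    p5_variant = "informative",
    p5_alternative = NULL,
    costs = costs,
    mcmc = mcmc_config(seed = as.integer(seed)),
    scenario = list(cohort_n = as.integer(sample(25:2000, 1L)),
                    batch_size = 3L,
                    grid = seq(25L, 500L, by = 25L)),
    markov = list(n0 = as.integer(sample(25:2000, 1L)),
                  horizon_years = 10L,
                  death_cumulative = stats::runif(1, 0, 0.95),
                  death_annualization = sample(c("uniform", "geometric"), 1L),
                  hearingloss_cumulative = stats::runif(1, 0, 0.2),
                  hearingloss_annualization = "geometric",
                  discount_rate = stats::runif(1, 0, 0.15)),
    published = NULL
  ), class = "scenario_config")
}

#' Validate a scenario configuration
#'
#' Checks every consuming module's invariants and reports the offending
#' field by name.
#'
#' @param config A `scenario_config` (or a plain list in the same shape).
#' @return The validated config, invisibly; errors otherwise.
#' @export
validate_scenario <- function(config) {
  req <- c("seed", "evidence", "costs", "mcmc", "scenario", "markov")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("scenario config is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!length(config$evidence))
    stop("field 'evidence' must hold at least one record", call. = FALSE)
  labs <- vapply(config$evidence, function(r) r$label, character(1))
  if (anyDuplicated(labs))
    stop("field 'evidence' has duplicated labels", call. = FALSE)
  for (r in config$evidence)
    if (!inherits(r, "evidence_record"))
      stop("field 'evidence' must hold evidence_record objects", call. = FALSE)
  if (!inherits(config$costs, "cost_inputs"))
    stop("field 'costs' must be a cost_inputs object", call. = FALSE)
  if (is.null(config$costs$discount_rate) || is.na(config$costs$discount_rate))
    stop("field 'discount_rate' is required", call. = FALSE)
  if (!inherits(config$mcmc, "mcmc_config"))
    stop("field 'mcmc' must be an mcmc_config", call. = FALSE)
  sc <- config$scenario
  if (is.null(sc$cohort_n) || sc$cohort_n < 1)
    stop("field 'scenario$cohort_n' must be at least 1", call. = FALSE)
  if (is.null(sc$batch_size) || sc$batch_size < 1)
    stop("field 'scenario$batch_size' must be at least 1", call. = FALSE)
  mk <- config$markov
  if (is.null(mk$n0) || mk$n0 < 0)
    stop("field 'markov$n0' must be non-negative", call. = FALSE)
  if (is.null(mk$death_cumulative) || mk$death_cumulative < 0 ||
      mk$death_cumulative >= 1)
    stop("field 'markov$death_cumulative' must lie in [0, 1)", call. = FALSE)
  if (is.null(mk$discount_rate) || mk$discount_rate < 0)
    stop("field 'markov$discount_rate' must be non-negative", call. = FALSE)
  invisible(config)
}
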