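# Beta-binomial posterior inference for the decision-tree arm probabilities.
#
# Each probability (P1..P6) carries a beta prior expressed as pseudo-counts
# (prior "events" / "no events") and a binomial observation (events /
# non-events). The posterior is sampled by a Metropolis-Hastings random walk
# on (0,1); beta-binomial conjugacy gives the exact closed form used as the
# oracle in tests and cross-checks.

#' Beta prior pseudo-counts
#'
#' A beta prior parameterized directly as pseudo-counts: `alpha` prior
#' "events" and `beta` prior "no events". No +1 offsets are applied; the
#' pseudo-counts enter the posterior additively.
#'
#' @param alpha Positive real, prior event pseudo-count.
#' @param beta Positive real, prior non-event pseudo-count.
#' @return An object of class `beta_prior` with fields `alpha` and `beta`.
#' @export
#' @examples
#' beta_prior(58, 91)
beta_prior <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive number", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_prior")
}

#' Non-informative beta prior
#'
#' Either the Jeffreys prior Beta(1/2, 1/2) (default) or the uniform
#' Beta(1, 1). Jeffreys is the package default for probabilities estimated
#' without prior evidence.
#'
#' @param kind `"jeffreys"` or `"uniform"`.
#' @return A `beta_prior`.
#' @export
noninformative_prior <- function(kind = c("jeffreys", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "jeffreys") beta_prior(0.5, 0.5) else beta_prior(1, 1)
}

#' Binomial observation
#'
#' @param events Non-negative integer count of events.
#' @param non_events Non-negative integer count of non-events.
#' @return An object of class `binom_obs`.
#' @export
binom_obs <- function(events, non_events) {
  for (nm in c("events", "non_events")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop(sprintf("'%s' must be a single non-negative integer", nm),
           call. = FALSE)
  }
  structure(list(events = as.numeric(events),
                 non_events = as.numeric(non_events)),
            class = "binom_obs")
}

#' Evidence record for one arm probability
#'
#' Bundles a label (e.g. `"P4"`), a binomial observation and a beta prior.
#'
#' @param label Character identifier, unique within a scenario.
#' @param obs A [binom_obs()].
#' @param prior A [beta_prior()], or `NULL` for the default non-informative
#'   prior (Jeffreys).
#' @return An object of class `evidence_record`.
#' @export
#' @examples
#' evidence_record("P4", binom_obs(26, 63), beta_prior(58, 91))
evidence_record <- function(label, obs, prior = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a non-empty string", call. = FALSE)
  if (!inherits(obs, "binom_obs"))
    stop("'obs' must be a binom_obs", call. = FALSE)
  if (is.null(prior)) prior <- noninformative_prior()
  if (!inherits(prior, "beta_prior"))
    stop("'prior' must be a beta_prior or NULL", call. = FALSE)
  structure(list(label = label, obs = obs, prior = prior),
            class = "evidence_record")
}

#' MCMC configuration
#'
#' @param iterations Total chain length (default 12500).
#' @param burn_in Iterations discarded before summarizing (default 2500).
#' @param proposal_sd Standard deviation of the Gaussian random-walk
#'   proposal (default 0.05).
#' @param tune If `TRUE` (default), a short pilot phase rescales
#'   `proposal_sd` until the acceptance rate falls in roughly 20-50%.
#' @param seed Integer seed; the chain is fully deterministic given it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 12500L, burn_in = 2500L,
                        proposal_sd = 0.05, tune = TRUE, seed = 1L) {
  if (!is.numeric(iterations) || iterations < 1 || iterations != round(iterations))
    stop("'iterations' must be a positive integer", call. = FALSE)
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in != round(burn_in))
    stop("'burn_in' must be a non-negative integer", call. = FALSE)
  if (burn_in >= iterations)
    stop("'burn_in' must be smaller than 'iterations'", call. = FALSE)
  if (!is.numeric(proposal_sd) || proposal_sd <= 0)
    stop("'proposal_sd' must be positive", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 proposal_sd = as.numeric(proposal_sd),
                 tune = isTRUE(tune),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Conjugate beta posterior (closed form)
#'
#' With a Beta(alpha, beta) prior and k events in k + m trials the posterior
#' is Beta(alpha + k, beta + m). Serves as the exact oracle for the sampler.
#'
#' @param prior A [beta_prior()].
#' @param obs A [binom_obs()].
#' @return A `beta_prior` holding the posterior shape parameters.
#' @export
#' @examples
#' conjugate_posterior(beta_prior(58, 91), binom_obs(26, 63)) # Beta(84, 154)
conjugate_posterior <- function(prior, obs) {
  if (!inherits(prior, "beta_prior"))
    stop("'prior' must be a beta_prior", call. = FALSE)
  if (!inherits(obs, "binom_obs"))
    stop("'obs' must be a binom_obs", call. = FALSE)
  beta_prior(prior$alpha + obs$events, prior$beta + obs$non_events)
}

#' Beta distribution quantile
#'
#' Quantile of Beta(alpha, beta) by numeric inversion of the regularized
#' incomplete beta function (via [stats::qbeta()]).
#'
#' @param params A [beta_prior()] holding the shape parameters.
#' @param q Probability level in (0, 1).
#' @return The q-quantile.
#' @export
beta_quantile <- function(params, q) {
  if (!inherits(params, "beta_prior"))
    stop("'params' must be a beta_prior", call. = FALSE)
  if (!is.numeric(q) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly inside (0, 1)", call. = FALSE)
  stats::qbeta(q, params$alpha, params$beta)
}

# Deterministic per-record sub-seed from a scenario seed, kept inside the
# 32-bit signed range. Distinct labels get distinct streams.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483629)
}

#' Metropolis-Hastings sampler for one arm probability
#'
#' Samples the beta-binomial posterior of an [evidence_record()] with a
#' Gaussian random-walk proposal on the unit interval; proposals outside
#' (0,1) are rejected (a zero prior outside the support). Deterministic for
#' a fixed `config$seed`.
#'
#' @param record An [evidence_record()].
#' @param config An [mcmc_config()].
#' @return An object of class `prob_samples`: post-burn-in `values`,
#'   `acceptance_rate`, the `proposal_sd` actually used, and the record
#'   `label`.
#' @export
#' @examples
#' rec <- evidence_record("P4", binom_obs(26, 63), beta_prior(58, 91))
#' s <- mh_sample(rec, mcmc_config(seed = 42))
#' summarize_samples(s)
mh_sample <- function(record, config = mcmc_config()) {
  if (!inherits(record, "evidence_record"))
    stop("'record' must be an evidence_record", call. = FALSE)
  if (!inherits(config, "mcmc_config"))
    stop("'config' must be an mcmc_config", call. = FALSE)

  post <- conjugate_posterior(record$prior, record$obs)
  a <- post$alpha; b <- post$beta
  log_post <- function(p) (a - 1) * log(p) + (b - 1) * log1p(-p)

  old_rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(config$seed)

  sd_prop <- config$proposal_sd
  start <- min(max(a / (a + b), 1e-6), 1 - 1e-6)

  run_chain <- function(n, p0, sd_prop) {
    eps <- stats::rnorm(n, 0, sd_prop)
    logu <- log(stats::runif(n))
    values <- numeric(n)
    p <- p0
    lp <- log_post(p)
    acc <- 0L
    for (i in seq_len(n)) {
      cand <- p + eps[i]
      if (cand > 0 && cand < 1) {
        lcand <- log_post(cand)
        if (logu[i] < lcand - lp) {
          p <- cand; lp <- lcand; acc <- acc + 1L
        }
      }
      values[i] <- p
    }
    list(values = values, acc = acc / n)
  }

  if (config$tune) {
    # pilot rounds target 20-50% acceptance; geometric rescaling
    p0 <- start
    for (round in 1:10) {
      pilot <- run_chain(400L, p0, sd_prop)
      p0 <- pilot$values[400L]
      if (pilot$acc < 0.20) sd_prop <- sd_prop * 0.5
      else if (pilot$acc > 0.50) sd_prop <- sd_prop * 2
      else break
    }
    start <- p0
  }

  chain <- run_chain(config$iterations, start, sd_prop)
  values <- chain$values[(config$burn_in + 1L):config$iterations]
  structure(list(values = values,
                 acceptance_rate = chain$acc,
                 proposal_sd = sd_prop,
                 label = record$label),
            class = "prob_samples")
}

#' Posterior summary: median and equal-tailed 95% credible interval
#'
#' @param samples A `prob_samples` object (or bare numeric vector).
#' @return An object of class `posterior_summary` with `median`, `ci_low`
#'   (2.5th percentile) and `ci_high` (97.5th percentile).
#' @export
summarize_samples <- function(samples) {
  v <- if (inherits(samples, "prob_samples")) samples$values else samples
  if (!is.numeric(v) || length(v) == 0L)
    stop("empty sample set", call. = FALSE)
  qs <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(median = qs[2], ci_low = qs[1], ci_high = qs[3]),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("median %.4f  (95%% CrI %.4f - %.4f)\n",
              x$median, x$ci_low, x$ci_high))
  invisible(x)
}

#' Chain diagnostics: acceptance rate, autocorrelation, effective sample size
#'
#' ESS uses the initial-positive-sequence estimator: the autocorrelation sum
#' is truncated at the first non-positive term of the pairwise sums. A chain
#' with zero variance (e.g. all proposals rejected) is flagged degenerate.
#'
#' @param samples A `prob_samples` object.
#' @param max_lag Highest lag of the reported autocorrelations.
#' @return A list with `acceptance_rate`, `autocorrelation` (named vector,
#'   lags 1..`max_lag`), `ess`, `n`, and logical `degenerate`; also
#'   rendered as a one-row data frame by `as.data.frame()`.
#' @export
mcmc_diagnostics <- function(samples, max_lag = 20L) {
  if (!inherits(samples, "prob_samples"))
    stop("'samples' must be a prob_samples object", call. = FALSE)
  v <- samples$values
  n <- length(v)
  if (n == 0L) stop("empty sample set", call. = FALSE)
  if (stats::var(v) == 0) {
    return(structure(list(acceptance_rate = samples$acceptance_rate,
                          autocorrelation = stats::setNames(rep(NA_real_, max_lag),
                                                            paste0("lag", seq_len(max_lag))),
                          ess = NA_real_, n = n, degenerate = TRUE,
                          label = samples$label),
                     class = "mcmc_diagnostics"))
  }
  lag_max <- min(max(max_lag, 50L), n - 1L)
  rho <- stats::acf(v, lag.max = lag_max, plot = FALSE)$acf[-1]
  # initial positive sequence: sum consecutive pairs while positive
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair <= 0) break
    s <- s + pair
  }
  ess <- min(n, n / (1 + 2 * s))
  structure(list(acceptance_rate = samples$acceptance_rate,
                 autocorrelation = stats::setNames(rho[seq_len(max_lag)],
                                                   paste0("lag", seq_len(max_lag))),
                 ess = ess, n = n, degenerate = FALSE,
                 label = samples$label),
            class = "mcmc_diagnostics")
}

#' @export
as.data.frame.mcmc_diagnostics <- function(x, ...) {
  data.frame(label = if (is.null(x$label)) NA_character_ else x$label,
             n = x$n,
             acceptance_rate = x$acceptance_rate,
             lag1_autocorr = unname(x$autocorrelation[1]),
             ess = x$ess,
             degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}

#' Posterior table for a set of evidence records
#'
#' Runs the sampler once per record (per-record sub-seeds derived from one
#' scenario seed) and returns the summary table mirroring the published
#' simulation-results layout, with diagnostics columns.
#'
#' @param records List of [evidence_record()]s.
#' @param config An [mcmc_config()]; its `seed` is the scenario seed.
#' @return Data frame with one row per record: label, median, ci_low,
#'   ci_high, acceptance_rate, ess, plus the conjugate-oracle median.
#' @export
posterior_table <- function(records, config = mcmc_config()) {
  stopifnot(length(records) > 0)
  labels <- vapply(records, function(r) r$label, character(1))
  if (anyDuplicated(labels))
    stop("record labels must be unique within a scenario", call. = FALSE)
  rows <- lapply(records, function(rec) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, rec$label)
    s <- mh_sample(rec, cfg)
    sm <- summarize_samples(s)
    d <- mcmc_diagnostics(s)
    data.frame(label = rec$label,
               median = sm$median, ci_low = sm$ci_low, ci_high = sm$ci_high,
               acceptance_rate = d$acceptance_rate, ess = d$ess,
               conjugate_median = beta_quantile(
                 conjugate_posterior(rec$prior, rec$obs), 0.5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
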