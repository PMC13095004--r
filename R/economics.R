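# First-year decision-tree economics: expected per-patient cost of the
# conventional cisplatin arm versus the genotype-guided arm, with
# batch-dependent genotyping unit costs, equipment amortization spread over
# the annual cohort, and the break-even cohort search.

#' Monetary model inputs
#'
#' All cost parameters of the model, in USD. Defaults are the published
#' summary inputs: cisplatin course 307.02, docetaxel course 270.29,
#' genotyping 26.27 (batches of 3) / 17.12 (batches of 5), real-time PCR
#' equipment 38,340 amortized straight-line at 20%/year (7,668/year),
#' hearing-aid care 73.81 per patient-year, and a 6.79% annual discount
#' rate.
#'
#' @param cddp_course_usd Cisplatin chemotherapy course cost per patient.
#' @param docetaxel_course_usd Docetaxel course cost per patient.
#' @param genotyping_unit_usd_by_batch Named numeric vector mapping batch
#'   size to per-patient assay cost.
#' @param equipment_usd Purchase price of the PCR system.
#' @param amortization_rate Straight-line amortization fraction per year.
#' @param annual_amortization_usd Annual equipment charge; must equal
#'   `equipment_usd * amortization_rate`.
#' @param hearing_annual_usd Annual audiological care cost per affected
#'   patient (one device).
#' @param first_year_oto_usd First-year ototoxicity management cost per
#'   affected patient (device acquisition, fitting, audiology). Not part of
#'   the published summary inputs; must be supplied by the scenario.
#' @param discount_rate Annual discount rate for future costs.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(cddp_course_usd = 307.02,
                        docetaxel_course_usd = 270.29,
                        genotyping_unit_usd_by_batch = c("3" = 26.27, "5" = 17.12),
                        equipment_usd = 38340,
                        amortization_rate = 0.20,
                        annual_amortization_usd = equipment_usd * amortization_rate,
                        hearing_annual_usd = 73.81,
                        first_year_oto_usd = NA_real_,
                        discount_rate = 0.0679) {
  money <- c(cddp_course_usd = cddp_course_usd,
             docetaxel_course_usd = docetaxel_course_usd,
             equipment_usd = equipment_usd,
             annual_amortization_usd = annual_amortization_usd,
             hearing_annual_usd = hearing_annual_usd)
  for (nm in names(money))
    if (!is.numeric(money[[nm]]) || money[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative number", nm), call. = FALSE)
  if (!is.na(first_year_oto_usd) && first_year_oto_usd < 0)
    stop("'first_year_oto_usd' must be non-negative", call. = FALSE)
  if (amortization_rate < 0 || amortization_rate > 1)
    stop("'amortization_rate' must lie in [0, 1]", call. = FALSE)
  if (abs(annual_amortization_usd - equipment_usd * amortization_rate) > 1e-6)
    stop("'annual_amortization_usd' must equal equipment_usd * amortization_rate",
         call. = FALSE)
  if (discount_rate < 0)
    stop("'discount_rate' must be non-negative", call. = FALSE)
  if (is.null(names(genotyping_unit_usd_by_batch)) ||
      any(genotyping_unit_usd_by_batch < 0))
    stop("'genotyping_unit_usd_by_batch' must be a named non-negative vector",
         call. = FALSE)
  structure(list(cddp_course_usd = cddp_course_usd,
                 docetaxel_course_usd = docetaxel_course_usd,
                 genotyping_unit_usd_by_batch = genotyping_unit_usd_by_batch,
                 equipment_usd = equipment_usd,
                 amortization_rate = amortization_rate,
                 annual_amortization_usd = annual_amortization_usd,
                 hearing_annual_usd = hearing_annual_usd,
                 first_year_oto_usd = first_year_oto_usd,
                 discount_rate = discount_rate),
            class = "cost_inputs")
}

#' Decision-tree arm probabilities
#'
#' The six chance-node probabilities of the first-year decision tree plus
#' the two annual follow-up risks: P1 high-risk genotype prevalence, P2/P3
#' dropout (death or loss to follow-up) under cisplatin/docetaxel, P4
#' moderate-to-severe ototoxicity under conventional care, P5 ototoxicity in
#' low-risk patients on cisplatin, P6 ototoxicity under docetaxel; T1/T2 the
#' annual death and background hearing-loss risks of the Markov follow-up.
#'
#' @param p1,p2,p3,p4,p5,p6 Probabilities in \[0, 1\].
#' @param t1_death_annual,t2_hearingloss_annual Annual risks in \[0, 1).
#' @return An object of class `arm_probabilities`.
#' @export
arm_probabilities <- function(p1, p2, p3, p4, p5, p6,
                              t1_death_annual = 0.077,
                              t2_hearingloss_annual = NA_real_) {
  ps <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6)
  for (nm in names(ps))
    if (!is.numeric(ps[[nm]]) || is.na(ps[[nm]]) || ps[[nm]] < 0 || ps[[nm]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm), call. = FALSE)
  for (nm in c("t1_death_annual", "t2_hearingloss_annual")) {
    v <- get(nm)
    if (!is.na(v) && (v < 0 || v >= 1))
      stop(sprintf("'%s' must lie in [0, 1)", nm), call. = FALSE)
  }
  structure(as.list(c(ps, t1_death_annual = t1_death_annual,
                      t2_hearingloss_annual = t2_hearingloss_annual)),
            class = "arm_probabilities")
}

#' Parametric genotyping batch-cost model
#'
#' Per-patient assay cost as a function of batch size: reagent cost covers
#' the patient samples, per-batch control reactions and a loss allowance;
#' per-batch labor is split across the patients in the batch.
#' Cost per patient = `reagent * (1 + loss) * (b + controls)/b + labor/b`,
#' non-increasing in batch size b.
#'
#' @param reagent_usd_per_test Reagent cost per reaction.
#' @param control_tests_per_batch Control reactions run with each batch.
#' @param loss_fraction Fraction of reactions lost and repeated (default 0.10).
#' @param labor_usd_per_batch Labor cost per batch.
#' @return An object of class `batch_cost_model`.
#' @export
batch_cost_model <- function(reagent_usd_per_test,
                             control_tests_per_batch = 2,
                             loss_fraction = 0.10,
                             labor_usd_per_batch = 0) {
  if (reagent_usd_per_test < 0 || labor_usd_per_batch < 0 ||
      control_tests_per_batch < 0)
    stop("batch-cost components must be non-negative", call. = FALSE)
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("'loss_fraction' must lie in [0, 1)", call. = FALSE)
  structure(list(reagent_usd_per_test = reagent_usd_per_test,
                 control_tests_per_batch = control_tests_per_batch,
                 loss_fraction = loss_fraction,
                 labor_usd_per_batch = labor_usd_per_batch),
            class = "batch_cost_model")
}

#' Per-patient genotyping cost for a batch size
#'
#' A lookup table (as in [cost_inputs()]) takes precedence; the parametric
#' [batch_cost_model()] is used for batch sizes absent from the lookup.
#'
#' @param batch_size Number of patient samples genotyped simultaneously.
#' @param lookup Named numeric vector (batch size -> cost), or `NULL`.
#' @param model A [batch_cost_model()], or `NULL`.
#' @return Per-patient assay cost in USD.
#' @export
#' @examples
#' genotyping_unit_cost(3) # 26.27
#' genotyping_unit_cost(5) # 17.12
genotyping_unit_cost <- function(batch_size,
                                 lookup = c("3" = 26.27, "5" = 17.12),
                                 model = NULL) {
  if (!is.numeric(batch_size) || batch_size < 1 || batch_size != round(batch_size))
    stop("'batch_size' must be a positive integer", call. = FALSE)
  key <- as.character(batch_size)
  if (!is.null(lookup) && key %in% names(lookup))
    return(unname(lookup[key]))
  if (is.null(model))
    stop(sprintf("batch size %d not in lookup and no parametric model supplied",
                 batch_size), call. = FALSE)
  b <- batch_size
  model$reagent_usd_per_test * (1 + model$loss_fraction) *
    (b + model$control_tests_per_batch) / b +
    model$labor_usd_per_batch / b
}

#' Expected first-year cost per patient, conventional arm
#'
#' All patients receive cisplatin; survivors who develop moderate-to-severe
#' ototoxicity incur the first-year management cost:
#' `cddp + (1 - P2) * P4 * H`.
#'
#' @param probs An [arm_probabilities()].
#' @param costs A [cost_inputs()]; `first_year_oto_usd` must be set.
#' @return Expected cost in USD per patient.
#' @export
expected_cost_conventional <- function(probs, costs) {
  H <- .oto_cost(costs)
  costs$cddp_course_usd + (1 - probs$p2) * probs$p4 * H
}

#' Expected first-year cost per patient, genotype-guided arm
#'
#' Every patient is genotyped (assay cost plus an equal share of the annual
#' equipment amortization); high-risk patients (P1) receive docetaxel,
#' low-risk patients cisplatin; ototoxicity arises at P5 among surviving
#' low-risk and P6 among surviving high-risk patients.
#'
#' @param probs An [arm_probabilities()].
#' @param costs A [cost_inputs()]; `first_year_oto_usd` must be set.
#' @param batch_size Genotyping batch size (looked up in `costs`).
#' @param cohort_n Annual cohort size over which amortization is spread.
#' @return Expected cost in USD per patient.
#' @export
expected_cost_genotyped <- function(probs, costs, batch_size = 3L,
                                    cohort_n = 250L) {
  if (!is.numeric(cohort_n) || cohort_n < 1)
    stop("'cohort_n' must be at least 1", call. = FALSE)
  H <- .oto_cost(costs)
  unit <- genotyping_unit_cost(batch_size,
                               lookup = costs$genotyping_unit_usd_by_batch)
  oto_share <- (1 - probs$p1) * (1 - probs$p2) * probs$p5 +
    probs$p1 * (1 - probs$p3) * probs$p6
  unit + costs$annual_amortization_usd / cohort_n +
    probs$p1 * costs$docetaxel_course_usd +
    (1 - probs$p1) * costs$cddp_course_usd +
    oto_share * H
}

.oto_cost <- function(costs) {
  if (!inherits(costs, "cost_inputs"))
    stop("'costs' must be a cost_inputs object", call. = FALSE)
  if (is.na(costs$first_year_oto_usd))
    stop("'first_year_oto_usd' is required for first-year arm costs; set it in cost_inputs()",
         call. = FALSE)
  costs$first_year_oto_usd
}

#' Per-patient cost difference at a given cohort size
#'
#' The conventional-minus-genotyped difference decomposes into a
#' cohort-independent variable saving K and the per-patient amortization
#' share: `K - amortization / N`. Positive values mean genotyping saves
#' money.
#'
#' @param variable_saving_k Cohort-independent per-patient saving (USD).
#' @param annual_amortization Annual equipment amortization (USD).
#' @param cohort_n Annual cohort size.
#' @return Per-patient difference in USD.
#' @export
per_patient_difference <- function(variable_saving_k, annual_amortization,
                                   cohort_n) {
  if (any(cohort_n < 1))
    stop("'cohort_n' must be at least 1", call. = FALSE)
  variable_saving_k - annual_amortization / cohort_n
}

#' Calibrate the variable saving from one reference difference
#'
#' Inverts [per_patient_difference()] at a reference cohort size:
#' `K = diff_at_ref + amortization / ref_n`. With K calibrated from any one
#' published row, the whole difference column follows.
#'
#' @param diff_at_ref Published per-patient difference at `ref_n`.
#' @param annual_amortization Annual equipment amortization (USD).
#' @param ref_n Reference cohort size.
#' @return The variable saving K in USD.
#' @export
#' @examples
#' calibrate_variable_saving(14.01, 7668, 500) # 29.346
calibrate_variable_saving <- function(diff_at_ref, annual_amortization, ref_n) {
  if (ref_n < 1) stop("'ref_n' must be at least 1", call. = FALSE)
  diff_at_ref + annual_amortization / ref_n
}

#' Break-even cohort size
#'
#' Smallest multiple of `step` at which the per-patient difference turns
#' positive, i.e. N > amortization / K on the grid.
#'
#' @param variable_saving_k Cohort-independent per-patient saving; must be
#'   positive for a break-even to exist.
#' @param annual_amortization Annual equipment amortization (USD).
#' @param step Grid step in patients (default 25).
#' @return Break-even cohort size (integer), or `NA` with a warning when
#'   `variable_saving_k <= 0` (genotyping never breaks even).
#' @export
#' @examples
#' break_even_cohort(29.346, 7668) # 275
break_even_cohort <- function(variable_saving_k, annual_amortization,
                              step = 25L) {
  if (step < 1 || step != round(step))
    stop("'step' must be a positive integer", call. = FALSE)
  if (variable_saving_k <= 0) {
    warning("variable saving is non-positive: no break-even cohort exists")
    return(NA_integer_)
  }
  if (annual_amortization <= 0) return(as.integer(step))
  n_star <- annual_amortization / variable_saving_k # diff > 0 iff N > n_star
  as.integer(step * (floor(n_star / step) + 1L))
}

#' Shift a difference to another batch size via the unit-cost gap
#'
#' Genotyping unit cost is the only batch-dependent term of the per-patient
#' difference, so `diff_new = diff_ref + (unit_ref - unit_new)`.
#'
#' @param diff_ref_batch Difference at the reference batch size (USD).
#' @param unit_cost_ref,unit_cost_new Per-patient assay costs (USD).
#' @return Difference at the new batch size in USD.
#' @export
#' @examples
#' batch_effect(14.01, 26.27, 17.12) # 23.16
batch_effect <- function(diff_ref_batch, unit_cost_ref, unit_cost_new) {
  if (unit_cost_ref < 0 || unit_cost_new < 0)
    stop("unit costs must be non-negative", call. = FALSE)
  diff_ref_batch + (unit_cost_ref - unit_cost_new)
}

#' First-year cost table over a cohort-size grid
#'
#' One row per cohort size with the genotype-arm expected cost, the
#' conventional-arm cost, the difference, and a break-even marker at the
#' first sign change.
#'
#' @param probs An [arm_probabilities()].
#' @param costs A [cost_inputs()] with `first_year_oto_usd` set.
#' @param batch_size Genotyping batch size.
#' @param cohort_grid Integer vector of cohort sizes (default 25..500 by 25).
#' @return Data frame with columns `cohort_n`, `cost_genotyped`,
#'   `cost_conventional`, `difference`, `break_even`.
#' @export
cohort_cost_table <- function(probs, costs, batch_size = 3L,
                              cohort_grid = seq(25L, 500L, by = 25L)) {
  if (length(cohort_grid) == 0) stop("empty cohort grid", call. = FALSE)
  conv <- expected_cost_conventional(probs, costs)
  geno <- vapply(cohort_grid, function(n)
    expected_cost_genotyped(probs, costs, batch_size, n), numeric(1))
  diff <- conv - geno
  data.frame(cohort_n = as.integer(cohort_grid),
             cost_genotyped = geno,
             cost_conventional = conv,
             difference = diff,
             break_even = diff > 0 & c(TRUE, diff[-length(diff)] <= 0))
}
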