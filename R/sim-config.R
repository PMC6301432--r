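#' Simulation configuration for a synthetic RDS network cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_population()], [run_rds_recruitment()], [evolve_ties()],
#' [emit_wave_tables()] and [simulate_cohort()]. Defaults emulate the study
#' conditions of a three-wave RDS cohort of young Black individuals assigned
#' male at birth who have sex with men, in which 7.6\% identify as
#' transgender women (TGW) and the rest as MSM: 62 seeds, a target Wave-1
#' sample of 618, wave-to-wave study retention of 86.4\% (MSM) and 66.7\%
#' (TGW), and roster caps of five confidants and five recent sexual partners
#' plus one primary partner.
#'
#' Per-tie retention probabilities default to the cohort's reported
#' stability ratios (confidant 0.334 TGW / 0.408 MSM; sexual 0.175 TGW /
#' 0.278 MSM) so that, with two visits and no tie arrivals, the expected
#' stability ratio of a simulated group equals its retention probability.
#' New-tie arrival rates default to values consistent with the reported
#' turnover ratios at typical roster sizes.
#'
#' @param population_size number of hidden-population members.
#' @param prop_tgw fraction of the hidden population identifying as TGW.
#' @param n_seeds number of RDS seeds.
#' @param coupons_per_recruit maximum coupons (recruits) per enrollee.
#' @param target_sample recruitment stops once this many are enrolled.
#' @param n_waves number of study waves (>= 1).
#' @param mixing 2x2 within/between-group tie-probability weights, rows and
#'   columns named `TGW`, `MSM`.
#' @param mean_confidant_degree,mean_sexual_degree expected degree of the
#'   initial confidant / sexual tie structures (within the hidden
#'   population).
#' @param retain_prob list `list(confidant = c(TGW=, MSM=), sexual = ...)`
#'   of per-interval tie persistence probabilities.
#' @param new_tie_rate same shape: expected new ties per ego per
#'   inter-wave interval.
#' @param attrition_retention named vector `c(TGW=, MSM=)`: probability an
#'   ego attends each wave after Wave 1.
#' @param covariate_prevalences per-group prevalence list for the baseline
#'   covariates (HIV+, employed, income under $20k, stable housing, ever
#'   jailed, insured, in a relationship).
#' @param external_pool_frac size of the external cis-women partner pool,
#'   as a fraction of `population_size`. These partners can appear on
#'   sexual rosters but are outside the hidden population (not recruitable,
#'   no confidant ties).
#' @param prop_external_partner per-group probability that a sexual tie
#'   attaches to the external pool rather than the hidden population.
#' @param alter_attr per-group probabilities for partnership and alter
#'   attributes (exchange sex, payment received, probability an alter's
#'   HIV status is known, partner-preference distributions).
#' @param primary_partner_prob probability an ego with any current sexual
#'   tie designates a primary partner at a wave.
#' @param covariate_missingness probability each optional covariate is
#'   missing for a respondent.
#' @param match_dropout probability a true cross-wave match record is not
#'   confirmed (0 = perfect confirmation).
#' @param seed_selection `"degree"` (seeds drawn proportionally to
#'   confidant degree, i.e. highly socially connected individuals) or
#'   `"uniform"`.
#' @param recruit_on `"confidant"` (coupons pass through social ties) or
#'   `"union"` of confidant and sexual ties.
#' @param rng_seed master seed; all stages derive named sub-streams.
#'
#' @return a validated object of class `netpanel_sim_config` (a list).
#' @export
sim_config <- function(population_size = 3000,
                       prop_tgw = 0.076,
                       n_seeds = 62,
                       coupons_per_recruit = 3,
                       target_sample = 618,
                       n_waves = 3,
                       mixing = matrix(c(1, 0.3, 0.3, 1), 2, 2,
                                       dimnames = list(c("TGW", "MSM"),
                                                       c("TGW", "MSM"))),
                       mean_confidant_degree = 8,
                       mean_sexual_degree = 4.3,
                       retain_prob = list(
                         confidant = c(TGW = 0.334, MSM = 0.408),
                         sexual    = c(TGW = 0.175, MSM = 0.278)),
                       new_tie_rate = list(
                         confidant = c(TGW = 0.65, MSM = 0.45),
                         sexual    = c(TGW = 0.10, MSM = 0.20)),
                       attrition_retention = c(TGW = 0.667, MSM = 0.864),
                       covariate_prevalences = list(
                         TGW = c(hiv_positive = 0.306, employed = 0.396,
                                 income_lt_20k = 0.935, stably_housed = 0.688,
                                 ever_jail = 0.521, insured = 0.587,
                                 in_relationship = 0.333),
                         MSM = c(hiv_positive = 0.423, employed = 0.711,
                                 income_lt_20k = 0.808, stably_housed = 0.754,
                                 ever_jail = 0.455, insured = 0.548,
                                 in_relationship = 0.399)),
                       external_pool_frac = 0.2,
                       prop_external_partner = c(TGW = 0.05, MSM = 0.15),
                       alter_attr = list(
                         exchange_sex     = c(TGW = 0.25, MSM = 0.10),
                         payment_received = c(TGW = 0.15, MSM = 0.05),
                         hiv_known_prob   = 0.7,
                         pref_dist = list(
                           TGW = c(men = 0.55, tgw = 0.25, cis_women = 0.10,
                                   other_unknown = 0.10),
                           MSM = c(men = 0.75, tgw = 0.03, cis_women = 0.12,
                                   other_unknown = 0.10),
                           EXT = c(men = 1, tgw = 0, cis_women = 0,
                                   other_unknown = 0))),
                       primary_partner_prob = 0.4,
                       covariate_missingness = 0.05,
                       match_dropout = 0,
                       seed_selection = c("degree", "uniform"),
                       recruit_on = c("confidant", "union"),
                       rng_seed = 1L) {
  cfg <- list(
    population_size = population_size, prop_tgw = prop_tgw,
    n_seeds = n_seeds, coupons_per_recruit = coupons_per_recruit,
    target_sample = target_sample, n_waves = n_waves, mixing = mixing,
    mean_confidant_degree = mean_confidant_degree,
    mean_sexual_degree = mean_sexual_degree,
    retain_prob = retain_prob, new_tie_rate = new_tie_rate,
    attrition_retention = attrition_retention,
    covariate_prevalences = covariate_prevalences,
    external_pool_frac = external_pool_frac,
    prop_external_partner = prop_external_partner,
    alter_attr = alter_attr,
    primary_partner_prob = primary_partner_prob,
    covariate_missingness = covariate_missingness,
    match_dropout = match_dropout,
    seed_selection = match.arg(seed_selection),
    recruit_on = match.arg(recruit_on),
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "netpanel_sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks all field constraints and reports the offending field by name.
#'
#' @param config a `netpanel_sim_config` or a plain list of the same fields
#'   (e.g. parsed from YAML), in which case missing fields take defaults.
#' @return the validated `netpanel_sim_config`.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "netpanel_sim_config")) {
    stopifnot(is.list(config))
    config <- do.call(sim_config, config)
    return(config)
  }
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  chk_count <- function(field, x, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != floor(x))
      fail(field, sprintf("must be a single integer >= %d", min))
  }
  chk_prob <- function(field, x) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
      fail(field, "must be probabilities in [0, 1]")
  }
  chk_nonneg <- function(field, x) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0))
      fail(field, "must be nonnegative")
  }
  chk_count("population_size", config$population_size)
  chk_count("n_seeds", config$n_seeds)
  chk_count("coupons_per_recruit", config$coupons_per_recruit, min = 0)
  chk_count("target_sample", config$target_sample)
  chk_count("n_waves", config$n_waves)
  chk_prob("prop_tgw", config$prop_tgw)
  if (config$n_seeds > config$target_sample)
    fail("n_seeds", "must not exceed target_sample")
  if (config$target_sample > config$population_size)
    fail("target_sample", "must not exceed population_size")
  if (!is.matrix(config$mixing) || !identical(dim(config$mixing), c(2L, 2L)) ||
      anyNA(config$mixing) || any(config$mixing < 0))
    fail("mixing", "must be a nonnegative 2x2 matrix")
  chk_nonneg("mean_confidant_degree", config$mean_confidant_degree)
  chk_nonneg("mean_sexual_degree", config$mean_sexual_degree)
  for (kind in c("confidant", "sexual")) {
    rp <- config$retain_prob[[kind]]
    if (is.null(rp) || !all(c("TGW", "MSM") %in% names(rp)))
      fail("retain_prob", sprintf("must map %s x {TGW, MSM}", kind))
    chk_prob("retain_prob", rp)
    nr <- config$new_tie_rate[[kind]]
    if (is.null(nr) || !all(c("TGW", "MSM") %in% names(nr)))
      fail("new_tie_rate", sprintf("must map %s x {TGW, MSM}", kind))
    chk_nonneg("new_tie_rate", nr)
  }
  if (!all(c("TGW", "MSM") %in% names(config$attrition_retention)))
    fail("attrition_retention", "must be named c(TGW=, MSM=)")
  chk_prob("attrition_retention", config$attrition_retention)
  chk_prob("external_pool_frac", config$external_pool_frac)
  chk_prob("prop_external_partner", config$prop_external_partner)
  chk_prob("primary_partner_prob", config$primary_partner_prob)
  chk_prob("covariate_missingness", config$covariate_missingness)
  chk_prob("match_dropout", config$match_dropout)
  for (g in c("TGW", "MSM")) chk_prob("covariate_prevalences",
                                      config$covariate_prevalences[[g]])
  config
}
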