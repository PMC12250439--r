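#' @title Model configuration building blocks
#' @description Constructors for the typed pieces of a model run. Each
#'   constructor performs hard validation (invariant violations stop with an
#'   error naming the offending field); soft consistency checks live in
#'   [validate_model_run()].
#' @name config-types
NULL

scenario_kinds <- c("reduced_wait", "missed_surgery", "lifesaving")
subgroup_kinds <- c(RWT = "reduced_wait", AMS = "missed_surgery",
                    MA = "lifesaving")

fail_field <- function(type, field, rule) {
  stop(sprintf("%s: field '%s' violates '%s'", type, field, rule),
       call. = FALSE)
}

check_scalar <- function(x, type, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail_field(type, field, "must be a single finite number")
  }
  as.numeric(x)
}

#' Discount settings
#'
#' @param annual_rate annual discount rate applied to both costs and QALYs,
#'   as a fraction per year. Default 0.035 (3.5 percent per year), the national
#'   guideline rate used throughout.
#' @return A `discount_settings` object.
#' @export
discount_settings <- function(annual_rate = 0.035) {
  annual_rate <- check_scalar(annual_rate, "DiscountSettings", "annual_rate")
  if (annual_rate < 0 || annual_rate >= 1) {
    fail_field("DiscountSettings", "annual_rate", "0 <= annual_rate < 1")
  }
  structure(list(annual_rate = annual_rate), class = "discount_settings")
}

#' Health-state utility profile for one subgroup
#'
#' Utilities are flat within segments. `u_wait` is the utility while on the
#' waiting list and includes any pre-operative stress decrement; `u_post_early`
#' and `u_post_delayed` are post-surgery utilities in the early and delayed
#' arms; `u_missed` is the utility of living without surgery, used only in the
#' missed-surgery scenario.
#'
#' @param u_wait,u_post_early,u_post_delayed,u_missed utilities in
#'   \eqn{[-1, 1]}; `u_post_delayed` and `u_missed` may be `NA` when the
#'   scenario does not use them.
#' @return A `utility_profile` object.
#' @export
utility_profile <- function(u_wait = NA_real_, u_post_early,
                            u_post_delayed = NA_real_, u_missed = NA_real_) {
  vals <- list(u_wait = u_wait, u_post_early = u_post_early,
               u_post_delayed = u_post_delayed, u_missed = u_missed)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L) fail_field("UtilityProfile", nm, "must be scalar")
    if (!is.na(v)) {
      v <- check_scalar(v, "UtilityProfile", nm)
      if (v < -1 || v > 1) fail_field("UtilityProfile", nm, "utility in [-1, 1]")
    }
    vals[[nm]] <- as.numeric(v)
  }
  structure(vals, class = "utility_profile")
}

#' Event timeline for one subgroup
#'
#' All times are years from model start (the perioperative period at the
#' initiative launch). `t_death_counterfactual` is death in the delayed or
#' missed arm; in the lifesaving scenario it must equal `t_early`, encoding
#' the assumption that a patient who would have died while waiting dies at
#' the scheduled early surgery date.
#'
#' @param t_early,t_delayed years to early / delayed surgery.
#' @param t_death_counterfactual,t_death_early years to death in the
#'   counterfactual and early arms.
#' @return A `timeline` object.
#' @export
timeline <- function(t_early, t_delayed, t_death_counterfactual,
                     t_death_early) {
  t_early <- check_scalar(t_early, "Timeline", "t_early")
  t_delayed <- check_scalar(t_delayed, "Timeline", "t_delayed")
  t_death_counterfactual <- check_scalar(t_death_counterfactual, "Timeline",
                                         "t_death_counterfactual")
  t_death_early <- check_scalar(t_death_early, "Timeline", "t_death_early")
  if (t_early < 0) fail_field("Timeline", "t_early", "t_early >= 0")
  if (t_delayed < t_early) {
    fail_field("Timeline", "t_delayed", "t_early <= t_delayed")
  }
  if (t_death_counterfactual < t_delayed) {
    fail_field("Timeline", "t_death_counterfactual",
               "t_delayed <= t_death_counterfactual")
  }
  if (t_death_early < t_death_counterfactual) {
    fail_field("Timeline", "t_death_early",
               "t_death_counterfactual <= t_death_early")
  }
  structure(list(t_early = t_early, t_delayed = t_delayed,
                 t_death_counterfactual = t_death_counterfactual,
                 t_death_early = t_death_early),
            class = "timeline")
}

cost_fields <- c("direct_early", "direct_delayed",
                 "indirect_patient_early", "indirect_patient_delayed",
                 "indirect_caregiver_early", "indirect_caregiver_delayed")

#' Per-patient cost inputs for one subgroup
#'
#' Early-arm and counterfactual-arm lump-sum amounts (currency units per
#' patient) for direct medical cost and for patient and caregiver
#' productivity losses, with the times at which each arm's costs are
#' incurred (used for discounting). Productivity losses are supplied as
#' pre-monetised human-capital amounts.
#'
#' @param direct_early,direct_delayed direct medical cost per patient.
#' @param indirect_patient_early,indirect_patient_delayed patient
#'   productivity loss per patient.
#' @param indirect_caregiver_early,indirect_caregiver_delayed caregiver
#'   productivity loss per patient.
#' @param incurrence_time_early,incurrence_time_delayed years from model
#'   start at which each arm's costs fall.
#' @return A `cost_set` object.
#' @export
cost_set <- function(direct_early = 0, direct_delayed = 0,
                     indirect_patient_early = 0, indirect_patient_delayed = 0,
                     indirect_caregiver_early = 0,
                     indirect_caregiver_delayed = 0,
                     incurrence_time_early = 0, incurrence_time_delayed = 0) {
  vals <- list(direct_early = direct_early, direct_delayed = direct_delayed,
               indirect_patient_early = indirect_patient_early,
               indirect_patient_delayed = indirect_patient_delayed,
               indirect_caregiver_early = indirect_caregiver_early,
               indirect_caregiver_delayed = indirect_caregiver_delayed,
               incurrence_time_early = incurrence_time_early,
               incurrence_time_delayed = incurrence_time_delayed)
  for (nm in names(vals)) vals[[nm]] <- check_scalar(vals[[nm]], "CostSet", nm)
  for (nm in cost_fields) {
    if (vals[[nm]] < 0) fail_field("CostSet", nm, "cost >= 0")
  }
  for (nm in c("incurrence_time_early", "incurrence_time_delayed")) {
    if (vals[[nm]] < 0) fail_field("CostSet", nm, "incurrence time >= 0")
  }
  structure(vals, class = "cost_set")
}

#' Parameters for one patient subgroup
#'
#' A subgroup is one of the three clinical pathways a cohort's patients can
#' follow: `RWT` (reduced waiting time, the general three-segment scenario),
#' `AMS` (avoided missed surgery: without the initiative the patient would
#' have become ineligible and lived unoperated), or `MA` (mortality averted:
#' the patient would have died while waiting). The subgroup kind fixes the
#' scenario; supplying a mismatching `scenario` is an error.
#'
#' @param kind `"RWT"`, `"AMS"` or `"MA"`.
#' @param n_patients number of patients on this pathway (non-negative; used
#'   as a population weight).
#' @param utilities a [utility_profile()].
#' @param timeline a [timeline()].
#' @param costs a [cost_set()].
#' @param scenario optional scenario label; must match the kind's scenario
#'   (`reduced_wait`, `missed_surgery`, `lifesaving` respectively).
#' @return A `subgroup_parameters` object.
#' @export
subgroup_parameters <- function(kind, n_patients, utilities, timeline, costs,
                                scenario = NULL) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% names(subgroup_kinds)) {
    fail_field("SubgroupParameters", "kind", "one of RWT, AMS, MA")
  }
  expected <- unname(subgroup_kinds[[kind]])
  if (is.null(scenario)) scenario <- expected
  if (!identical(scenario, expected)) {
    stop(sprintf(paste0("SubgroupParameters: kind '%s' requires scenario ",
                        "'%s', got '%s'"), kind, expected, scenario),
         call. = FALSE)
  }
  n_patients <- check_scalar(n_patients, "SubgroupParameters", "n_patients")
  if (n_patients < 0) {
    fail_field("SubgroupParameters", "n_patients", "n_patients >= 0")
  }
  if (!inherits(utilities, "utility_profile")) {
    fail_field("SubgroupParameters", "utilities", "must be a utility_profile")
  }
  if (!inherits(timeline, "timeline")) {
    fail_field("SubgroupParameters", "timeline", "must be a timeline")
  }
  if (!inherits(costs, "cost_set")) {
    fail_field("SubgroupParameters", "costs", "must be a cost_set")
  }
  if (scenario == "reduced_wait" && is.na(utilities$u_post_delayed)) {
    fail_field("SubgroupParameters", "utilities$u_post_delayed",
               "required for the reduced_wait scenario")
  }
  if (scenario == "reduced_wait" && is.na(utilities$u_wait)) {
    fail_field("SubgroupParameters", "utilities$u_wait",
               "required for the reduced_wait scenario")
  }
  if (scenario == "missed_surgery" && is.na(utilities$u_missed)) {
    fail_field("SubgroupParameters", "utilities$u_missed",
               "required for the missed_surgery scenario")
  }
  if (costs$incurrence_time_early > timeline$t_death_early ||
      costs$incurrence_time_delayed > timeline$t_death_early) {
    fail_field("SubgroupParameters", "costs",
               "incurrence times within [0, t_death_early]")
  }
  if (scenario == "lifesaving" &&
      timeline$t_death_counterfactual != timeline$t_early) {
    stop(paste("SubgroupParameters: the lifesaving scenario assumes death in",
               "the no-surgery arm coincides with the scheduled early surgery",
               "date; set t_death_counterfactual equal to t_early"),
         call. = FALSE)
  }
  structure(list(kind = kind, scenario = scenario, n_patients = n_patients,
                 utilities = utilities, timeline = timeline, costs = costs),
            class = "subgroup_parameters")
}

#' One surgical intervention with its patient subgroups
#'
#' @param name cohort label (e.g. one of the five priority interventions, or
#'   any user-defined surgery).
#' @param subgroups list of [subgroup_parameters()]; at least one, with
#'   unique kinds.
#' @return A `surgery_cohort` object.
#' @export
surgery_cohort <- function(name, subgroups) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    fail_field("SurgeryCohort", "name", "non-empty label")
  }
  if (!is.list(subgroups) || length(subgroups) == 0L) {
    fail_field("SurgeryCohort", "subgroups", "at least one subgroup")
  }
  ok <- vapply(subgroups, inherits, logical(1), "subgroup_parameters")
  if (!all(ok)) {
    fail_field("SurgeryCohort", "subgroups",
               "all elements must be subgroup_parameters")
  }
  kinds <- vapply(subgroups, `[[`, character(1), "kind")
  if (anyDuplicated(kinds)) {
    fail_field("SurgeryCohort", "subgroups", "subgroup kinds must be unique")
  }
  names(subgroups) <- kinds
  structure(list(name = name, subgroups = subgroups),
            class = "surgery_cohort")
}

#' Economy-wide settings
#'
#' @param gdp_per_capita GDP per capita (currency units per person-year),
#'   used to monetise QALY gains in the benefit-cost ratio.
#' @param wtp_threshold willingness-to-pay threshold (currency per QALY).
#' @param currency_label display label only; no conversion is performed.
#' @return An `economy_settings` object.
#' @export
economy_settings <- function(gdp_per_capita, wtp_threshold,
                             currency_label = "EGP") {
  gdp_per_capita <- check_scalar(gdp_per_capita, "EconomySettings",
                                 "gdp_per_capita")
  wtp_threshold <- check_scalar(wtp_threshold, "EconomySettings",
                                "wtp_threshold")
  if (gdp_per_capita <= 0) {
    fail_field("EconomySettings", "gdp_per_capita", "gdp_per_capita > 0")
  }
  if (wtp_threshold <= 0) {
    fail_field("EconomySettings", "wtp_threshold", "wtp_threshold > 0")
  }
  if (!is.character(currency_label) || length(currency_label) != 1L) {
    fail_field("EconomySettings", "currency_label", "must be a string")
  }
  structure(list(gdp_per_capita = gdp_per_capita,
                 wtp_threshold = wtp_threshold,
                 currency_label = currency_label),
            class = "economy_settings")
}

#' A complete, validated model run description
#'
#' @param cohorts non-empty list of [surgery_cohort()]s.
#' @param discount a [discount_settings()].
#' @param economy an [economy_settings()].
#' @return A `model_run` object.
#' @export
model_run <- function(cohorts, discount = discount_settings(), economy) {
  if (!is.list(cohorts) || length(cohorts) == 0L) {
    fail_field("ModelRun", "cohorts", "non-empty list of cohorts")
  }
  ok <- vapply(cohorts, inherits, logical(1), "surgery_cohort")
  if (!all(ok)) {
    fail_field("ModelRun", "cohorts", "all elements must be surgery_cohort")
  }
  nms <- vapply(cohorts, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    fail_field("ModelRun", "cohorts", "cohort names must be unique")
  }
  names(cohorts) <- nms
  if (!inherits(discount, "discount_settings")) {
    fail_field("ModelRun", "discount", "must be discount_settings")
  }
  if (!inherits(economy, "economy_settings")) {
    fail_field("ModelRun", "economy", "must be economy_settings")
  }
  structure(list(cohorts = cohorts, discount = discount, economy = economy),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat("<model_run>\n")
  cat(sprintf("  cohorts: %d | discount rate: %.4g/yr | WTP: %s %s/QALY\n",
              length(x$cohorts), x$discount$annual_rate,
              x$economy$currency_label,
              format(x$economy$wtp_threshold, big.mark = ",")))
  for (co in x$cohorts) {
    kinds <- vapply(co$subgroups, function(s) {
      sprintf("%s(n=%g)", s$kind, s$n_patients)
    }, character(1))
    cat(sprintf("  - %s: %s\n", co$name, paste(kinds, collapse = ", ")))
  }
  invisible(x)
}

#' Soft consistency checks on a model run
#'
#' Returns human-readable warnings for configurations that are legal but
#' suspicious, e.g. a waiting-list utility above the post-operative utility
#' (surgery apparently makes patients worse off). Hard invariant violations
#' are caught at construction/load time, not here.
#'
#' @param run a [model_run()].
#' @return Character vector of warnings (empty when fully consistent).
#' @export
validate_model_run <- function(run) {
  stopifnot(inherits(run, "model_run"))
  warnings <- character(0)
  for (co in run$cohorts) {
    for (sg in co$subgroups) {
      u <- sg$utilities
      where <- sprintf("cohort '%s' subgroup %s", co$name, sg$kind)
      if (!is.na(u$u_wait) && u$u_wait > u$u_post_early) {
        warnings <- c(warnings, sprintf(
          "%s: u_wait (%g) exceeds u_post_early (%g); surgery appears harmful",
          where, u$u_wait, u$u_post_early))
      }
      if (sg$scenario == "missed_surgery" && !is.na(u$u_missed) &&
          u$u_missed > u$u_post_early) {
        warnings <- c(warnings, sprintf(
          "%s: u_missed (%g) exceeds u_post_early (%g)",
          where, u$u_missed, u$u_post_early))
      }
    }
  }
  warnings
}
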