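#' @title Incremental cost engine
#' @description Each cost component's increment is the discounted early-arm
#'   amount minus the discounted counterfactual amount, so savings are
#'   negative. The societal total adds patient and caregiver productivity
#'   losses to the direct medical increment; the payer total is the direct
#'   increment alone.
#' @name cost-engine
NULL

cost_breakdown <- function(delta_direct, delta_indirect_patient,
                           delta_indirect_caregiver) {
  structure(list(
    delta_direct = delta_direct,
    delta_indirect_patient = delta_indirect_patient,
    delta_indirect_caregiver = delta_indirect_caregiver,
    delta_total_societal = delta_direct + delta_indirect_patient +
      delta_indirect_caregiver,
    delta_total_payer = delta_direct),
    class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %s: %.2f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Per-patient and population incremental costs for one subgroup
#'
#' Every increment is
#' `discount_lump(early amount, incurrence_time_early) -
#'  discount_lump(counterfactual amount, incurrence_time_delayed)`.
#' Scenario handling of the counterfactual arm:
#' \itemize{
#'   \item `reduced_wait`: counterfactual amounts used as given (the delayed
#'     surgery still happens and still costs money);
#'   \item `missed_surgery`: no surgery occurs in the counterfactual, so its
#'     direct surgical cost defaults to 0 at load time but remains
#'     overridable (e.g. ongoing palliative care); counterfactual indirect
#'     losses are kept as given;
#'   \item `lifesaving`: the counterfactual patient dies at the early-surgery
#'     date, so all counterfactual components are zeroed.
#' }
#'
#' @param sp a [subgroup_parameters()].
#' @param d a [discount_settings()].
#' @return List with `per_patient` and `population` [cost_breakdown]s.
#' @export
subgroup_costs <- function(sp, d) {
  stopifnot(inherits(sp, "subgroup_parameters"),
            inherits(d, "discount_settings"))
  cs <- sp$costs
  r <- d$annual_rate
  cf_scale <- if (sp$scenario == "lifesaving") 0 else 1
  delta <- function(early, counterfactual) {
    discount_lump(early, cs$incurrence_time_early, r) -
      cf_scale * discount_lump(counterfactual, cs$incurrence_time_delayed, r)
  }
  pp <- cost_breakdown(
    delta_direct = delta(cs$direct_early, cs$direct_delayed),
    delta_indirect_patient = delta(cs$indirect_patient_early,
                                   cs$indirect_patient_delayed),
    delta_indirect_caregiver = delta(cs$indirect_caregiver_early,
                                     cs$indirect_caregiver_delayed))
  pop <- cost_breakdown(
    delta_direct = pp$delta_direct * sp$n_patients,
    delta_indirect_patient = pp$delta_indirect_patient * sp$n_patients,
    delta_indirect_caregiver = pp$delta_indirect_caregiver * sp$n_patients)
  list(per_patient = pp, population = pop)
}
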