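#' @title Reported outcomes
#' @description Combines incremental QALYs and costs into the framework's
#'   headline outcomes: incremental cost-effectiveness ratios (ICERs) from
#'   the societal and payer perspectives, the benefit-cost ratio (BCR), net
#'   monetary benefit (NMB), dominance classification, and a cost-
#'   effectiveness verdict against the willingness-to-pay (WTP) threshold.
#' @name outcomes
NULL

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Degenerate denominators are encoded as markers, never exceptions:
#' `dominant` (QALYs gained, money saved), `dominated` (QALYs lost, money
#' spent), `undefined` (zero QALY increment).
#'
#' @param delta_cost incremental cost (currency units).
#' @param delta_qalys incremental QALYs.
#' @return List of class `icer` with `value` (the ratio, `NA` when the QALY
#'   increment is zero) and `flag` (one of `"none"`, `"dominant"`,
#'   `"dominated"`, `"undefined"`).
#' @examples
#' compute_icer(2264156090, 48385)  # ~ 46795 per QALY
#' compute_icer(-5, 10)             # dominant
#' @export
compute_icer <- function(delta_cost, delta_qalys) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qalys))
  if (delta_qalys == 0) {
    out <- list(value = NA_real_, flag = "undefined")
  } else {
    flag <- if (delta_qalys > 0 && delta_cost < 0) {
      "dominant"
    } else if (delta_qalys < 0 && delta_cost > 0) {
      "dominated"
    } else {
      "none"
    }
    out <- list(value = delta_cost / delta_qalys, flag = flag)
  }
  structure(out, class = "icer")
}

#' @export
print.icer <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("<icer: undefined (zero QALY increment)>\n"))
  } else {
    cat(sprintf("<icer: %.0f per QALY%s>\n", x$value,
                if (x$flag == "none") "" else paste0(" [", x$flag, "]")))
  }
  invisible(x)
}

#' Benefit-cost ratio from the societal perspective
#'
#' `(delta_qalys * gdp_per_capita) / delta_total_societal`: monetised QALY
#' gains over incremental societal cost. A negative denominator (the
#' programme saves money overall) is reported as the signed ratio plus a
#' `cost_saving` flag rather than collapsed into a dominance verdict, so
#' both the plain ratio and the cost-saving fact stay representable.
#'
#' @param delta_qalys incremental QALYs.
#' @param gdp_per_capita currency units per person-year.
#' @param delta_total_societal incremental societal cost.
#' @return List of class `bcr` with `value` and `flag` (`"none"`,
#'   `"cost_saving"`, or `"undefined"` for a zero denominator).
#' @export
compute_bcr <- function(delta_qalys, gdp_per_capita, delta_total_societal) {
  stopifnot(is.finite(delta_qalys), is.finite(gdp_per_capita),
            gdp_per_capita > 0, is.finite(delta_total_societal))
  if (delta_total_societal == 0) {
    out <- list(value = NA_real_, flag = "undefined")
  } else {
    out <- list(value = delta_qalys * gdp_per_capita / delta_total_societal,
                flag = if (delta_total_societal < 0) "cost_saving" else "none")
  }
  structure(out, class = "bcr")
}

#' Assemble the outcome set for one evaluation unit
#'
#' @param delta_qalys population incremental QALYs.
#' @param costs a population-scale [cost_breakdown].
#' @param economy an [economy_settings()].
#' @return List of class `outcome_set`: QALY and cost totals, both ICERs,
#'   the BCR, NMB at the configured WTP, the dominance flag and the
#'   cost-effectiveness verdict (societal perspective).
#' @export
outcome_set <- function(delta_qalys, costs, economy) {
  stopifnot(inherits(costs, "cost_breakdown"),
            inherits(economy, "economy_settings"))
  icer_soc <- compute_icer(costs$delta_total_societal, delta_qalys)
  icer_pay <- compute_icer(costs$delta_total_payer, delta_qalys)
  bcr <- compute_bcr(delta_qalys, economy$gdp_per_capita,
                     costs$delta_total_societal)
  dominance <- if (delta_qalys > 0 && costs$delta_total_societal < 0) {
    "dominant"
  } else if (delta_qalys < 0 && costs$delta_total_societal > 0) {
    "dominated"
  } else {
    "none"
  }
  out <- structure(list(
    total_delta_qalys = delta_qalys,
    delta_direct = costs$delta_direct,
    delta_indirect_patient = costs$delta_indirect_patient,
    delta_indirect_caregiver = costs$delta_indirect_caregiver,
    delta_total_societal = costs$delta_total_societal,
    delta_total_payer = costs$delta_total_payer,
    icer_societal = icer_soc,
    icer_payer = icer_pay,
    bcr_societal = bcr,
    # NMB is an auxiliary linearisation of the WTP decision rule, stable
    # when the QALY increment is near zero (not a headline outcome)
    nmb = delta_qalys * economy$wtp_threshold - costs$delta_total_societal,
    dominance_flag = dominance,
    cost_effective_at_wtp = NA), class = "outcome_set")
  out$cost_effective_at_wtp <-
    classify_cost_effectiveness(out, economy$wtp_threshold)
  out
}

#' Cost-effectiveness verdict against a WTP threshold
#'
#' `TRUE` iff the unit is dominant, or its societal ICER is defined with a
#' positive QALY increment and does not exceed the threshold (boundary
#' equality counts as cost-effective).
#'
#' @param outcome an [outcome_set()].
#' @param wtp willingness-to-pay threshold (currency per QALY).
#' @return Logical scalar.
#' @export
classify_cost_effectiveness <- function(outcome, wtp) {
  stopifnot(inherits(outcome, "outcome_set"), is.finite(wtp), wtp > 0)
  if (outcome$dominance_flag == "dominant") return(TRUE)
  if (outcome$dominance_flag == "dominated") return(FALSE)
  icer <- outcome$icer_societal
  if (is.na(icer$value) || outcome$total_delta_qalys <= 0) return(FALSE)
  icer$value <= wtp
}

#' @export
print.outcome_set <- function(x, ...) {
  cat("<outcome_set>\n")
  cat(sprintf("  delta QALYs: %.2f\n", x$total_delta_qalys))
  cat(sprintf("  delta cost (societal): %.0f  (payer: %.0f)\n",
              x$delta_total_societal, x$delta_total_payer))
  fmt_icer <- function(ic) {
    if (is.na(ic$value)) "undefined" else sprintf("%.0f", ic$value)
  }
  cat(sprintf("  ICER societal: %s | payer: %s | dominance: %s\n",
              fmt_icer(x$icer_societal), fmt_icer(x$icer_payer),
              x$dominance_flag))
  cat(sprintf("  BCR: %s | NMB: %.0f | cost-effective at WTP: %s\n",
              if (is.na(x$bcr_societal$value)) "undefined"
              else sprintf("%.2f", x$bcr_societal$value),
              x$nmb, x$cost_effective_at_wtp))
  invisible(x)
}
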