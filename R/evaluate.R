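#' @title Full-pipeline evaluation
#' @description Evaluates every subgroup of every cohort, aggregates to
#'   cohort and composite level, and exposes the result both as typed
#'   objects and as a flat results table. Population aggregation follows
#'   the weighted-sum rule: QALYs and costs are summed across subgroups and
#'   cohorts at the population level first, and ratios (ICER, BCR) are
#'   formed from those sums — per-cohort ICERs are never averaged.
#' @name evaluate
NULL

evaluate_subgroup <- function(sp, d) {
  q <- subgroup_qalys(sp, d)
  cst <- subgroup_costs(sp, d)
  list(qalys = q, costs = cst)
}

#' Evaluate a model run end-to-end
#'
#' @param run a [model_run()].
#' @param rate_override optional discount-rate override (e.g. `0` for the
#'   undiscounted variant); `NULL` uses the run's configured rate.
#' @return An object of class `cea_results`: `composite` (the population
#'   [outcome_set()] over all cohorts), `cohorts` (named list of per-cohort
#'   outcome sets), `subgroups` (data frame of per-subgroup detail at
#'   per-patient and population scale) and the `run` itself.
#' @export
evaluate_model_run <- function(run, rate_override = NULL) {
  stopifnot(inherits(run, "model_run"))
  if (length(run$cohorts) == 0L) {
    stop("evaluate_model_run: empty cohort list", call. = FALSE)
  }
  d <- run$discount
  if (!is.null(rate_override)) d <- discount_settings(rate_override)

  sub_rows <- list()
  cohort_outcomes <- list()
  agg_q <- 0
  agg <- c(delta_direct = 0, delta_indirect_patient = 0,
           delta_indirect_caregiver = 0)
  for (co in run$cohorts) {
    co_q <- 0
    co_c <- c(delta_direct = 0, delta_indirect_patient = 0,
              delta_indirect_caregiver = 0)
    for (sg in co$subgroups) {
      ev <- evaluate_subgroup(sg, d)
      pop <- ev$costs$population
      co_q <- co_q + ev$qalys$population
      co_c <- co_c + c(delta_direct = pop$delta_direct,
                       delta_indirect_patient = pop$delta_indirect_patient,
                       delta_indirect_caregiver = pop$delta_indirect_caregiver)
      seg <- ev$qalys$breakdown$segments
      sub_rows[[length(sub_rows) + 1L]] <- data.frame(
        cohort = co$name, subgroup = sg$kind, scenario = sg$scenario,
        n_patients = sg$n_patients,
        qalys_per_patient = ev$qalys$per_patient,
        qalys_population = ev$qalys$population,
        segments = paste(sprintf("%s=%.6g", names(seg), seg),
                         collapse = ";"),
        delta_direct_per_patient = ev$costs$per_patient$delta_direct,
        delta_indirect_patient_per_patient =
          ev$costs$per_patient$delta_indirect_patient,
        delta_indirect_caregiver_per_patient =
          ev$costs$per_patient$delta_indirect_caregiver,
        delta_total_societal_per_patient =
          ev$costs$per_patient$delta_total_societal,
        delta_direct_population = pop$delta_direct,
        delta_indirect_patient_population = pop$delta_indirect_patient,
        delta_indirect_caregiver_population = pop$delta_indirect_caregiver,
        delta_total_societal_population = pop$delta_total_societal,
        stringsAsFactors = FALSE)
    }
    cohort_outcomes[[co$name]] <- outcome_set(
      co_q, cost_breakdown(co_c[["delta_direct"]],
                           co_c[["delta_indirect_patient"]],
                           co_c[["delta_indirect_caregiver"]]),
      run$economy)
    agg_q <- agg_q + co_q
    agg <- agg + co_c
  }
  composite <- outcome_set(
    agg_q, cost_breakdown(agg[["delta_direct"]],
                          agg[["delta_indirect_patient"]],
                          agg[["delta_indirect_caregiver"]]),
    run$economy)
  structure(list(composite = composite, cohorts = cohort_outcomes,
                 subgroups = do.call(rbind, sub_rows), run = run,
                 annual_rate = d$annual_rate),
            class = "cea_results")
}

#' Aggregate already-evaluated cohort outcomes into a composite
#'
#' Sums population QALYs and cost components across cohorts and forms the
#' composite ratios from the sums. Exposed separately so alternative cohort
#' subsets can be aggregated without re-evaluating subgroups.
#'
#' @param run the [model_run()] supplying the economy settings.
#' @param cohort_outcomes named list of per-cohort [outcome_set()]s.
#' @return A composite [outcome_set()].
#' @export
aggregate_outcomes <- function(run, cohort_outcomes) {
  stopifnot(inherits(run, "model_run"))
  if (length(cohort_outcomes) == 0L) {
    stop("aggregate_outcomes: empty cohort list", call. = FALSE)
  }
  q <- sum(vapply(cohort_outcomes, `[[`, numeric(1), "total_delta_qalys"))
  comp <- function(f) sum(vapply(cohort_outcomes, `[[`, numeric(1), f))
  outcome_set(q, cost_breakdown(comp("delta_direct"),
                                comp("delta_indirect_patient"),
                                comp("delta_indirect_caregiver")),
              run$economy)
}

outcome_row <- function(name, o) {
  data.frame(
    unit = name,
    total_delta_qalys = o$total_delta_qalys,
    delta_direct = o$delta_direct,
    delta_indirect_patient = o$delta_indirect_patient,
    delta_indirect_caregiver = o$delta_indirect_caregiver,
    delta_total_societal = o$delta_total_societal,
    delta_total_payer = o$delta_total_payer,
    icer_societal = o$icer_societal$value,
    icer_societal_flag = o$icer_societal$flag,
    icer_payer = o$icer_payer$value,
    icer_payer_flag = o$icer_payer$flag,
    bcr_societal = o$bcr_societal$value,
    bcr_flag = o$bcr_societal$flag,
    nmb = o$nmb,
    dominance = o$dominance_flag,
    cost_effective_at_wtp = o$cost_effective_at_wtp,
    stringsAsFactors = FALSE)
}

#' Flat results table: one row per cohort plus a composite row
#'
#' ICERs are carried unrounded; display rounding to whole currency units is
#' left to the caller (the CLI rounds for its summary output).
#'
#' @param results a `cea_results` object from [evaluate_model_run()].
#' @return A data frame.
#' @export
results_table <- function(results) {
  stopifnot(inherits(results, "cea_results"))
  rows <- lapply(names(results$cohorts), function(nm) {
    outcome_row(nm, results$cohorts[[nm]])
  })
  rows[[length(rows) + 1L]] <- outcome_row("composite", results$composite)
  do.call(rbind, rows)
}

#' @export
print.cea_results <- function(x, ...) {
  cat(sprintf("<cea_results: %d cohorts, discount rate %.4g/yr>\n",
              length(x$cohorts), x$annual_rate))
  cat("composite:\n")
  print(x$composite)
  invisible(x)
}
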