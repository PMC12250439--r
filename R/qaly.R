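#' @title Incremental QALY segment engine
#' @description Incremental QALYs between the early-surgery arm and its
#'   counterfactual are the discounted areas between the two arms' flat
#'   health-state curves, split into the intervals over which the arms
#'   diverge. The general (reduced-wait) scenario has three segments:
#'   \describe{
#'     \item{A}{between early and delayed surgery — the waiting-time gap,
#'       weighted by `u_post_early - u_wait` (pre-operative stress included
#'       in `u_wait`);}
#'     \item{B}{from delayed surgery to death in the counterfactual arm —
#'       any residual post-operative difference, weighted by
#'       `u_post_early - u_post_delayed`;}
#'     \item{C}{the survival gap between the two arms' deaths, weighted by
#'       the full `u_post_early`.}
#'   }
#'   The missed-surgery scenario collapses B away (segments V, W) and the
#'   lifesaving scenario keeps only the survival gap (segment X).
#' @name qaly-engine
NULL

segment_breakdown <- function(segments, scenario) {
  # left-associative accumulation keeps the total bit-identical to the
  # vectorised PSA evaluator's arithmetic
  total <- Reduce(`+`, unname(as.list(segments)))
  structure(list(segments = segments, total = total, scenario = scenario),
            class = "segment_breakdown")
}

#' @export
print.segment_breakdown <- function(x, ...) {
  cat(sprintf("<segment_breakdown: %s>\n", x$scenario))
  for (nm in names(x$segments)) {
    cat(sprintf("  %s: %.6f QALYs\n", nm, x$segments[[nm]]))
  }
  cat(sprintf("  total: %.6f QALYs\n", x$total))
  invisible(x)
}

#' Incremental QALYs for the reduced-waiting-time scenario
#'
#' @param u a [utility_profile()] with `u_wait`, `u_post_early` and
#'   `u_post_delayed` set.
#' @param tl a [timeline()].
#' @param d a [discount_settings()].
#' @return A `segment_breakdown` with components `A`, `B`, `C` and their
#'   `total` (discounted QALYs per patient).
#' @export
qalys_reduced_wait <- function(u, tl, d) {
  stopifnot(inherits(u, "utility_profile"), inherits(tl, "timeline"),
            inherits(d, "discount_settings"))
  if (is.na(u$u_wait) || is.na(u$u_post_delayed)) {
    stop("qalys_reduced_wait: u_wait and u_post_delayed are required",
         call. = FALSE)
  }
  r <- d$annual_rate
  A <- (u$u_post_early - u$u_wait) *
    discounted_exposure(tl$t_early, tl$t_delayed, r)
  B <- (u$u_post_early - u$u_post_delayed) *
    discounted_exposure(tl$t_delayed, tl$t_death_counterfactual, r)
  C <- u$u_post_early *
    discounted_exposure(tl$t_death_counterfactual, tl$t_death_early, r)
  segment_breakdown(c(A = A, B = B, C = C), "reduced_wait")
}

#' Incremental QALYs for the avoided-missed-surgery scenario
#'
#' Without the initiative the patient lives unoperated at utility `u_missed`
#' until the counterfactual death. Segment V spans early surgery to that
#' death (the reduced-wait segment A with segment B empty); segment W is the
#' survival gap (segment C analogue).
#'
#' @inheritParams qalys_reduced_wait
#' @return A `segment_breakdown` with components `V`, `W` and `total`.
#' @export
qalys_missed_surgery <- function(u, tl, d) {
  stopifnot(inherits(u, "utility_profile"), inherits(tl, "timeline"),
            inherits(d, "discount_settings"))
  if (is.na(u$u_missed)) {
    stop("qalys_missed_surgery: u_missed is required", call. = FALSE)
  }
  r <- d$annual_rate
  V <- (u$u_post_early - u$u_missed) *
    discounted_exposure(tl$t_early, tl$t_death_counterfactual, r)
  W <- u$u_post_early *
    discounted_exposure(tl$t_death_counterfactual, tl$t_death_early, r)
  segment_breakdown(c(V = V, W = W), "missed_surgery")
}

#' Incremental QALYs for the lifesaving scenario
#'
#' The counterfactual patient dies at the scheduled early-surgery date
#' (`t_death_counterfactual == t_early`, enforced), so the whole gain is one
#' survival-gap segment X at utility `u_post_early`.
#'
#' @inheritParams qalys_reduced_wait
#' @return A `segment_breakdown` with component `X` and `total`.
#' @export
qalys_lifesaving <- function(u, tl, d) {
  stopifnot(inherits(u, "utility_profile"), inherits(tl, "timeline"),
            inherits(d, "discount_settings"))
  if (tl$t_death_counterfactual != tl$t_early) {
    stop(paste("qalys_lifesaving: the lifesaving scenario assumes death in",
               "the no-surgery arm coincides with the scheduled early",
               "surgery date (t_death_counterfactual == t_early)"),
         call. = FALSE)
  }
  r <- d$annual_rate
  X <- u$u_post_early * discounted_exposure(tl$t_early, tl$t_death_early, r)
  segment_breakdown(c(X = X), "lifesaving")
}

#' Per-patient and population incremental QALYs for one subgroup
#'
#' Dispatches on the subgroup's scenario and scales the per-patient total by
#' the subgroup's patient count.
#'
#' @param sp a [subgroup_parameters()].
#' @param d a [discount_settings()].
#' @return List with `breakdown` (the per-patient `segment_breakdown`),
#'   `per_patient` and `population` totals.
#' @export
subgroup_qalys <- function(sp, d) {
  stopifnot(inherits(sp, "subgroup_parameters"))
  bd <- switch(sp$scenario,
    reduced_wait = qalys_reduced_wait(sp$utilities, sp$timeline, d),
    missed_surgery = qalys_missed_surgery(sp$utilities, sp$timeline, d),
    lifesaving = qalys_lifesaving(sp$utilities, sp$timeline, d),
    stop(sprintf("subgroup_qalys: unknown scenario '%s'", sp$scenario),
         call. = FALSE))
  list(breakdown = bd, per_patient = bd$total,
       population = bd$total * sp$n_patients)
}
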