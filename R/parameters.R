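#' @title Addressable model parameters
#' @description Sensitivity analyses need to perturb individual inputs of a
#'   [model_run()]. Parameters are addressed by path strings of the form
#'   `"cohort/subgroup/block/field"` (e.g.
#'   `"open_heart_surgery/RWT/costs/direct_early"`) or
#'   `"cohort/subgroup/n_patients"`. Setting a parameter re-validates the
#'   whole run, so structurally impossible perturbations surface as errors
#'   rather than silently corrupt runs.
#'
#'   Two timeline fields are structurally tied and move together when set:
#'   in the lifesaving scenario `t_death_counterfactual` is pinned to
#'   `t_early`, and in the missed-surgery scenario the (unused) `t_delayed`
#'   tracks `t_death_counterfactual`.
#'
#'   Besides the four absolute timeline fields, three *duration* views are
#'   addressable and are the preferred targets for sensitivity analyses,
#'   because scaling a non-negative duration can never invert the event
#'   order: `timeline/wait_duration` (`t_delayed - t_early`),
#'   `timeline/post_delayed_duration`
#'   (`t_death_counterfactual - t_delayed`) and `timeline/survival_gap`
#'   (`t_death_early - t_death_counterfactual`). Setting a duration moves
#'   every later event, preserving the other durations.
#' @name parameters
NULL

duration_fields <- c("wait_duration", "post_delayed_duration",
                     "survival_gap")

timeline_durations <- function(tl) {
  c(wait_duration = tl$t_delayed - tl$t_early,
    post_delayed_duration = tl$t_death_counterfactual - tl$t_delayed,
    survival_gap = tl$t_death_early - tl$t_death_counterfactual)
}

split_path <- function(path) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1L]]
  if (length(parts) == 3L && parts[[3L]] == "n_patients") {
    list(cohort = parts[[1L]], subgroup = parts[[2L]], block = "n_patients",
         field = "n_patients")
  } else if (length(parts) == 4L &&
             parts[[3L]] %in% c("utilities", "timeline", "costs")) {
    list(cohort = parts[[1L]], subgroup = parts[[2L]], block = parts[[3L]],
         field = parts[[4L]])
  } else {
    stop(sprintf("unresolvable parameter path '%s'", path), call. = FALSE)
  }
}

locate_subgroup <- function(run, p, path) {
  co <- run$cohorts[[p$cohort]]
  if (is.null(co)) {
    stop(sprintf("parameter path '%s': no cohort '%s'", path, p$cohort),
         call. = FALSE)
  }
  sg <- co$subgroups[[p$subgroup]]
  if (is.null(sg)) {
    stop(sprintf("parameter path '%s': cohort '%s' has no subgroup '%s'",
                 path, p$cohort, p$subgroup), call. = FALSE)
  }
  sg
}

#' Read one parameter from a model run
#'
#' @param run a [model_run()].
#' @param path parameter path string.
#' @return Numeric scalar.
#' @export
get_parameter <- function(run, path) {
  p <- split_path(path)
  sg <- locate_subgroup(run, p, path)
  val <- if (p$block == "n_patients") {
    sg$n_patients
  } else if (p$block == "timeline" && p$field %in% duration_fields) {
    timeline_durations(sg$timeline)[[p$field]]
  } else {
    sg[[p$block]][[p$field]]
  }
  if (is.null(val)) {
    stop(sprintf("parameter path '%s': no field '%s'", path, p$field),
         call. = FALSE)
  }
  val
}

#' Set one parameter in a model run (revalidating)
#'
#' @param run a [model_run()].
#' @param path parameter path string.
#' @param value new numeric value.
#' @return A new, fully re-validated [model_run()].
#' @export
set_parameter <- function(run, path, value) {
  p <- split_path(path)
  sg <- locate_subgroup(run, p, path)  # errors early on a bad path
  doc <- model_run_to_list(run)
  ci <- which(vapply(doc$cohorts, `[[`, character(1), "name") == p$cohort)
  si <- which(vapply(doc$cohorts[[ci]]$subgroups, `[[`, character(1),
                     "kind") == p$subgroup)
  node <- doc$cohorts[[ci]]$subgroups[[si]]
  if (p$block == "n_patients") {
    node$n_patients <- value
  } else {
    if (is.null(node[[p$block]][[p$field]]) && p$block == "utilities") {
      # allow introducing an optional utility that was absent
      node[[p$block]][[p$field]] <- NA_real_
    } else if (is.null(node[[p$block]][[p$field]])) {
      stop(sprintf("parameter path '%s': no field '%s'", path, p$field),
           call. = FALSE)
    }
    if (p$block == "timeline" && p$field %in% duration_fields) {
      dur <- timeline_durations(sg$timeline)
      dur[[p$field]] <- value
      t_e <- sg$timeline$t_early
      node$timeline <- list(
        t_early = t_e,
        t_delayed = t_e + dur[["wait_duration"]],
        t_death_counterfactual = t_e + dur[["wait_duration"]] +
          dur[["post_delayed_duration"]],
        t_death_early = t_e + dur[["wait_duration"]] +
          dur[["post_delayed_duration"]] + dur[["survival_gap"]])
    } else {
      node[[p$block]][[p$field]] <- value
    }
    if (p$block == "timeline") {
      if (sg$scenario == "lifesaving" && p$field == "t_early") {
        node$timeline$t_death_counterfactual <- value
        node$timeline$t_delayed <- value
      }
      if (sg$scenario == "missed_surgery" &&
          p$field == "t_death_counterfactual") {
        node$timeline$t_delayed <- value
      }
    }
  }
  doc$cohorts[[ci]]$subgroups[[si]] <- node
  model_run_from_list(doc)
}

#' Enumerate the perturbable parameter paths of a model run
#'
#' Lists every numeric input that enters the formulas for at least one
#' scenario: the utilities the scenario can reference, the free timeline
#' fields (structurally tied fields are excluded), and all cost fields.
#' Patient counts are excluded (they are population weights, not sampled
#' quantities) but can be addressed explicitly.
#'
#' @param run a [model_run()].
#' @return Character vector of paths.
#' @export
enumerate_parameter_paths <- function(run) {
  stopifnot(inherits(run, "model_run"))
  paths <- character(0)
  for (co in run$cohorts) {
    for (sg in co$subgroups) {
      base <- paste(co$name, sg$kind, sep = "/")
      u <- sg$utilities
      u_fields <- names(unclass(u))[!vapply(unclass(u), is.na, logical(1))]
      tl_fields <- switch(sg$scenario,
        reduced_wait = c("t_early", "wait_duration",
                         "post_delayed_duration", "survival_gap"),
        missed_surgery = c("t_early", "wait_duration", "survival_gap"),
        lifesaving = c("t_early", "survival_gap"))
      paths <- c(paths,
                 paste(base, "utilities", u_fields, sep = "/"),
                 paste(base, "timeline", tl_fields, sep = "/"),
                 paste(base, "costs", names(unclass(sg$costs)), sep = "/"))
    }
  }
  paths
}
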