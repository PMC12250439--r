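#' @title Deterministic one-way sensitivity analysis (tornado)
#' @description Each addressed parameter is varied to `mean * (1 - delta)`
#'   and `mean * (1 + delta)` (base delta 0.10) with every other input held
#'   at base case; the full pipeline is re-evaluated each time and the
#'   composite societal ICER recorded. Entries are ranked by the width of
#'   the resulting ICER interval, the ordering a tornado diagram displays.
#' @name dsa
NULL

#' Run a one-way deterministic sensitivity analysis
#'
#' Perturbations that would violate a structural invariant (e.g. pushing a
#' delayed-surgery date before the early one) are flagged infeasible rather
#' than silently clamped; their ICER on that side is `NA` and they sort
#' last.
#'
#' @param run a [model_run()] whose base-case composite QALY gain is
#'   positive (the composite ICER must be well-defined).
#' @param paths parameter paths to vary; defaults to every perturbable
#'   input ([enumerate_parameter_paths()]).
#' @param relative_delta relative perturbation in (0, 1); default 0.10.
#' @return An object of class `dsa_result`: a data frame `entries` with
#'   columns `parameter_path`, `value_low`, `value_high`, `icer_low`,
#'   `icer_high`, `bar_width`, `infeasible`, sorted by `bar_width`
#'   descending, plus `base_icer` and `relative_delta`.
#' @export
run_dsa <- function(run, paths = enumerate_parameter_paths(run),
                    relative_delta = 0.10) {
  stopifnot(inherits(run, "model_run"))
  if (!is.numeric(relative_delta) || relative_delta <= 0 ||
      relative_delta >= 1) {
    stop("run_dsa: relative_delta must lie in (0, 1)", call. = FALSE)
  }
  base <- evaluate_model_run(run)
  if (is.na(base$composite$icer_societal$value) ||
      base$composite$total_delta_qalys <= 0) {
    stop("run_dsa: base-case composite QALY gain must be positive",
         call. = FALSE)
  }
  base_icer <- base$composite$icer_societal$value

  icer_at <- function(path, value) {
    perturbed <- tryCatch(set_parameter(run, path, value),
                          error = function(e) NULL)
    if (is.null(perturbed)) return(NA_real_)
    evaluate_model_run(perturbed)$composite$icer_societal$value
  }
  rows <- lapply(paths, function(path) {
    m <- get_parameter(run, path)
    lo_val <- m * (1 - relative_delta)
    hi_val <- m * (1 + relative_delta)
    icer_lo <- icer_at(path, lo_val)
    icer_hi <- icer_at(path, hi_val)
    data.frame(parameter_path = path, base_value = m,
               value_low = lo_val, value_high = hi_val,
               icer_low = icer_lo, icer_high = icer_hi,
               bar_width = abs(icer_hi - icer_lo),
               infeasible = is.na(icer_lo) || is.na(icer_hi),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries <- entries[order(-entries$bar_width, entries$parameter_path,
                           na.last = TRUE), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, base_icer = base_icer,
                 relative_delta = relative_delta),
            class = "dsa_result")
}

#' @export
print.dsa_result <- function(x, n = 10L, ...) {
  cat(sprintf("<dsa_result: %d parameters, delta %.0f%%, base ICER %.0f>\n",
              nrow(x$entries), 100 * x$relative_delta, x$base_icer))
  print(utils::head(x$entries[, c("parameter_path", "icer_low", "icer_high",
                                  "bar_width")], n))
  invisible(x)
}
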