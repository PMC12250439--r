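#' @title Catastrophic health expenditure (budget-share method)
#' @description An out-of-pocket (OOP) payment is catastrophic for a
#'   household when it exceeds a stated share of the household's total
#'   annual expenditure (10% or 25%; 25% is the base case). This is the
#'   budget-share method recommended for SDG indicator 3.8.2. The normative
#'   and partial-normative variants (which deduct subsistence needs) are
#'   recognised extension points but intentionally not implemented.
#' @name che
NULL

#' Household expenditure distribution
#'
#' Either an empirical vector of household annual total expenditures or a
#' lognormal parametric form.
#'
#' @param values empirical expenditures (all positive), or `NULL`.
#' @param meanlog,sdlog lognormal parameters (used when `values` is `NULL`);
#'   `sdlog` must be positive.
#' @return An `expenditure_distribution` object.
#' @export
expenditure_distribution <- function(values = NULL, meanlog = NULL,
                                     sdlog = NULL) {
  if (!is.null(values)) {
    if (!is.numeric(values) || length(values) == 0L ||
        any(!is.finite(values)) || any(values <= 0)) {
      stop("expenditure_distribution: empirical values must be positive",
           call. = FALSE)
    }
    out <- list(form = "empirical", values = as.numeric(values))
  } else {
    if (is.null(meanlog) || is.null(sdlog) || !is.finite(meanlog) ||
        !is.finite(sdlog) || sdlog <= 0) {
      stop("expenditure_distribution: need meanlog and positive sdlog",
           call. = FALSE)
    }
    out <- list(form = "lognormal", meanlog = meanlog, sdlog = sdlog)
  }
  structure(out, class = "expenditure_distribution")
}

#' Is an out-of-pocket payment catastrophic for one household?
#'
#' Strict inequality at the boundary: a payment exactly equal to the
#' threshold share is not catastrophic ("exceeding" is read strictly, and
#' the convention is fixed so results are bit-reproducible).
#'
#' @param oop out-of-pocket payment (currency units, non-negative).
#' @param household_expenditure household annual total expenditure
#'   (positive).
#' @param threshold catastrophic share in (0, 1); 0.25 is the base case.
#' @return Logical scalar.
#' @export
is_catastrophic <- function(oop, household_expenditure, threshold = 0.25) {
  stopifnot(is.finite(oop), oop >= 0, is.finite(threshold))
  if (!is.finite(household_expenditure) || household_expenditure <= 0) {
    stop("is_catastrophic: household_expenditure must be positive",
         call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("is_catastrophic: threshold must lie in (0, 1)", call. = FALSE)
  }
  oop > threshold * household_expenditure
}

#' Proportion of households facing catastrophic expenditure
#'
#' A household with expenditure `E` faces CHE for price `oop` at share
#' `threshold` iff `oop > threshold * E`, i.e. iff `E < oop / threshold`.
#' The empirical form returns the exact fraction of households below that
#' cutoff; the lognormal form evaluates its CDF at the cutoff.
#'
#' @param oop out-of-pocket price of the intervention.
#' @param dist an [expenditure_distribution()].
#' @param threshold catastrophic share in (0, 1).
#' @return List of class `che_result`: `threshold`,
#'   `proportion_catastrophic` and `affordable_proportion` (their sum is 1).
#' @export
proportion_catastrophic <- function(oop, dist, threshold = 0.25) {
  stopifnot(inherits(dist, "expenditure_distribution"),
            is.finite(oop), oop >= 0)
  if (threshold <= 0 || threshold >= 1) {
    stop("proportion_catastrophic: threshold must lie in (0, 1)",
         call. = FALSE)
  }
  cutoff <- oop / threshold
  p <- switch(dist$form,
    empirical = mean(dist$values < cutoff),
    lognormal = stats::plnorm(cutoff, dist$meanlog, dist$sdlog),
    stop("proportion_catastrophic: unknown distribution form",
         call. = FALSE))
  structure(list(threshold = threshold, proportion_catastrophic = p,
                 affordable_proportion = 1 - p),
            class = "che_result")
}

#' @export
print.che_result <- function(x, ...) {
  cat(sprintf(
    "<che_result: threshold %.0f%% | catastrophic %.1f%% | affordable %.1f%%>\n",
    100 * x$threshold, 100 * x$proportion_catastrophic,
    100 * x$affordable_proportion))
  invisible(x)
}

#' CHE table over interventions and thresholds
#'
#' @param oop named vector of out-of-pocket prices (one per intervention).
#' @param dist an [expenditure_distribution()].
#' @param thresholds catastrophic shares to report (base case 0.25, with
#'   0.10 alongside).
#' @return Data frame with one row per intervention and threshold.
#' @export
che_table <- function(oop, dist, thresholds = c(0.10, 0.25)) {
  stopifnot(is.numeric(oop), length(oop) > 0)
  if (is.null(names(oop))) names(oop) <- paste0("intervention_",
                                                seq_along(oop))
  rows <- lapply(names(oop), function(nm) {
    do.call(rbind, lapply(thresholds, function(th) {
      res <- proportion_catastrophic(oop[[nm]], dist, th)
      data.frame(intervention = nm, oop = oop[[nm]], threshold = th,
                 proportion_catastrophic = res$proportion_catastrophic,
                 affordable_proportion = res$affordable_proportion,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Read a household expenditure file
#'
#' Plain text, one positive expenditure per line; comment lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return An empirical [expenditure_distribution()].
#' @export
read_expenditure_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) == 0L || any(is.na(vals))) {
    stop(sprintf("read_expenditure_file: '%s' must contain one positive %s",
                 path, "number per line"), call. = FALSE)
  }
  expenditure_distribution(values = vals)
}
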