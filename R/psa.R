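#' @title Probabilistic sensitivity analysis
#' @description Parameter uncertainty is propagated by Monte Carlo: every
#'   addressed input is given a sampling distribution by the standard
#'   assignment rule — beta for utilities and proportions, normal for
#'   demographic/time variables, gamma for costs — parameterised from its
#'   mean and standard error by the method of moments. Each draw samples
#'   all inputs independently, re-evaluates the composite population
#'   outcome, and records the (incremental QALYs, incremental societal
#'   cost) pair; 5000 draws is the default. Draws that violate structural
#'   invariants (e.g. an inverted event order from a normal time draw) are
#'   rejected and redrawn, with a logged count.
#' @name psa
NULL

#' Sampling distribution specification for one parameter
#'
#' @param family `"beta"`, `"normal"` or `"gamma"`.
#' @param mean distribution mean (the base-case value).
#' @param spread standard error; `0` yields a degenerate point mass at the
#'   mean regardless of family.
#' @param label optional name used in diagnostics.
#' @return A `distribution_spec` object.
#' @export
distribution_spec <- function(family, mean, spread, label = NULL) {
  if (!family %in% c("beta", "normal", "gamma")) {
    stop("distribution_spec: family must be beta, normal or gamma",
         call. = FALSE)
  }
  stopifnot(is.finite(mean), is.finite(spread))
  if (spread < 0) {
    stop("distribution_spec: spread must be >= 0", call. = FALSE)
  }
  structure(list(family = family, mean = mean, spread = spread,
                 label = label),
            class = "distribution_spec")
}

#' Method-of-moments sampler parameters for a distribution spec
#'
#' Beta shapes require `spread^2 < mean * (1 - mean)` and a mean strictly
#' inside (0, 1); gamma uses `shape = mean^2/spread^2`,
#' `scale = spread^2/mean`; normal passes mean and spread through. A zero
#' spread short-circuits to a point mass.
#'
#' @param spec a [distribution_spec()].
#' @return List of sampler parameters (with a `family` element, possibly
#'   `"degenerate"`).
#' @export
moment_match <- function(spec) {
  stopifnot(inherits(spec, "distribution_spec"))
  who <- if (is.null(spec$label)) spec$family else spec$label
  m <- spec$mean
  s <- spec$spread
  if (s == 0) {
    return(list(family = "degenerate", value = m))
  }
  switch(spec$family,
    beta = {
      if (m <= 0 || m >= 1) {
        stop(sprintf("moment_match: '%s': beta mean must lie in (0, 1)",
                     who), call. = FALSE)
      }
      if (s^2 >= m * (1 - m)) {
        stop(sprintf(
          "moment_match: '%s': infeasible beta moments (spread^2 %.4g >= %s)",
          who, s^2, "mean*(1-mean)"), call. = FALSE)
      }
      k <- m * (1 - m) / s^2 - 1
      list(family = "beta", shape1 = m * k, shape2 = (1 - m) * k)
    },
    gamma = {
      if (m <= 0) {
        stop(sprintf("moment_match: '%s': gamma mean must be > 0", who),
             call. = FALSE)
      }
      list(family = "gamma", shape = (m / s)^2, scale = s^2 / m)
    },
    normal = list(family = "normal", mean = m, sd = s))
}

#' Draw samples from a distribution spec
#'
#' @param spec a [distribution_spec()].
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  p <- moment_match(spec)
  switch(p$family,
    degenerate = rep(p$value, n),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    normal = stats::rnorm(n, p$mean, p$sd))
}

#' Default distribution assignment for a model run
#'
#' Applies the family assignment rule to every perturbable path and sets
#' each spread to `spread_frac` of the mean (default 10%, mirroring the
#' one-way analysis band; override per parameter by editing the returned
#' list). Parameters with mean 0 become point masses. Patient counts are
#' not sampled.
#'
#' @param run a [model_run()].
#' @param spread_frac standard error as a fraction of the mean.
#' @return Named list of [distribution_spec()]s keyed by parameter path.
#' @export
default_psa_distributions <- function(run, spread_frac = 0.10) {
  stopifnot(is.finite(spread_frac), spread_frac >= 0)
  paths <- enumerate_parameter_paths(run)
  specs <- lapply(paths, function(path) {
    p <- split_path(path)
    family <- if (p$block == "utilities") {
      "beta"
    } else if (p$block == "timeline" ||
               p$field %in% c("incurrence_time_early",
                              "incurrence_time_delayed")) {
      "normal"
    } else {
      "gamma"
    }
    m <- get_parameter(run, path)
    distribution_spec(family, m, abs(m) * spread_frac, label = path)
  })
  names(specs) <- paths
  specs
}

# ---- vectorised pipeline evaluation over sampled draws ----

vec_exposure <- function(t0, t1, rate) {
  if (rate == 0) return(t1 - t0)
  ((1 + rate)^(-t0) - (1 + rate)^(-t1)) / log1p(rate)
}

flatten_run <- function(run) {
  lapply(unname(run$cohorts), function(co) {
    lapply(unname(co$subgroups), function(sg) {
      list(path_prefix = paste(co$name, sg$kind, sep = "/"),
           scenario = sg$scenario, n = sg$n_patients,
           u = unclass(sg$utilities), tl = unclass(sg$timeline),
           cs = unclass(sg$costs))
    })
  })
}

# Evaluate all subgroups for a block of draws. `cohort_recs` comes from
# flatten_run() (records grouped by cohort so the accumulation order
# mirrors the deterministic pipeline exactly); `samples` is a named list
# (parameter path -> vector of length n). Returns per-draw composite
# increments plus a feasibility mask and violation attribution counts.
evaluate_draws <- function(cohort_recs, samples, n, rate) {
  dq <- numeric(n)
  dc_dir <- numeric(n)
  dc_ip <- numeric(n)
  dc_ic <- numeric(n)
  feasible <- rep(TRUE, n)
  violations <- integer(0)
  note_violation <- function(viol, path) {
    if (!any(viol)) return()
    cur <- violations
    cur[path] <- (if (path %in% names(cur)) cur[[path]] else 0L) + sum(viol)
    violations <<- cur
  }
  field_vec <- function(rec, block, field, base) {
    path <- paste(rec$path_prefix, block, field, sep = "/")
    v <- samples[[path]]
    if (is.null(v)) rep(base, n) else v
  }
  has_sample <- function(rec, block, field) {
    !is.null(samples[[paste(rec$path_prefix, block, field, sep = "/")]])
  }
  eval_subgroup_draws <- function(rec) {
    u_pe <- field_vec(rec, "utilities", "u_post_early", rec$u$u_post_early)
    dur <- timeline_durations(rec$tl)
    t_e <- field_vec(rec, "timeline", "t_early", rec$tl$t_early)
    # event times are built from sampled durations so that time uncertainty
    # cannot invert the event order; explicitly sampled absolute fields
    # take precedence and are order-checked below
    # draws that sit exactly at the base values resolve to the base
    # absolute times, so a degenerate PSA reproduces the deterministic
    # pipeline bit-for-bit
    reconstruct <- function(base_abs, prev, prev_base, dur_vec, dur_base) {
      out <- prev + dur_vec
      out[prev == prev_base & dur_vec == dur_base] <- base_abs
      out
    }
    if (rec$scenario == "lifesaving") {
      t_d <- t_e
      t_dc <- t_e
    } else {
      t_d <- if (has_sample(rec, "timeline", "t_delayed")) {
        field_vec(rec, "timeline", "t_delayed", rec$tl$t_delayed)
      } else {
        reconstruct(rec$tl$t_delayed, t_e, rec$tl$t_early,
                    field_vec(rec, "timeline", "wait_duration",
                              dur[["wait_duration"]]),
                    dur[["wait_duration"]])
      }
      t_dc <- if (has_sample(rec, "timeline", "t_death_counterfactual")) {
        field_vec(rec, "timeline", "t_death_counterfactual",
                  rec$tl$t_death_counterfactual)
      } else if (rec$scenario == "missed_surgery") {
        t_d
      } else {
        reconstruct(rec$tl$t_death_counterfactual, t_d, rec$tl$t_delayed,
                    field_vec(rec, "timeline", "post_delayed_duration",
                              dur[["post_delayed_duration"]]),
                    dur[["post_delayed_duration"]])
      }
    }
    t_de <- if (has_sample(rec, "timeline", "t_death_early")) {
      field_vec(rec, "timeline", "t_death_early", rec$tl$t_death_early)
    } else {
      reconstruct(rec$tl$t_death_early, t_dc,
                  rec$tl$t_death_counterfactual,
                  field_vec(rec, "timeline", "survival_gap",
                            dur[["survival_gap"]]),
                  dur[["survival_gap"]])
    }
    blame <- function(dur_field, abs_field) {
      if (has_sample(rec, "timeline", abs_field)) abs_field else dur_field
    }
    tl_paths <- paste(rec$path_prefix, "timeline",
                      c("t_early",
                        blame("wait_duration", "t_delayed"),
                        blame("post_delayed_duration",
                              "t_death_counterfactual"),
                        blame("survival_gap", "t_death_early")), sep = "/")
    bad_e <- t_e < 0
    bad_d <- t_d < t_e
    bad_dc <- t_dc < t_d
    bad_de <- t_de < t_dc
    note_violation(bad_e, tl_paths[[1L]])
    note_violation(bad_d, tl_paths[[2L]])
    note_violation(bad_dc, tl_paths[[3L]])
    note_violation(bad_de, tl_paths[[4L]])
    ok <- !(bad_e | bad_d | bad_dc | bad_de)

    q <- switch(rec$scenario,
      reduced_wait = {
        u_w <- field_vec(rec, "utilities", "u_wait", rec$u$u_wait)
        u_pd <- field_vec(rec, "utilities", "u_post_delayed",
                          rec$u$u_post_delayed)
        (u_pe - u_w) * vec_exposure(t_e, t_d, rate) +
          (u_pe - u_pd) * vec_exposure(t_d, t_dc, rate) +
          u_pe * vec_exposure(t_dc, t_de, rate)
      },
      missed_surgery = {
        u_m <- field_vec(rec, "utilities", "u_missed", rec$u$u_missed)
        (u_pe - u_m) * vec_exposure(t_e, t_dc, rate) +
          u_pe * vec_exposure(t_dc, t_de, rate)
      },
      lifesaving = u_pe * vec_exposure(t_e, t_de, rate))

    ite <- field_vec(rec, "costs", "incurrence_time_early",
                     rec$cs$incurrence_time_early)
    itd <- field_vec(rec, "costs", "incurrence_time_delayed",
                     rec$cs$incurrence_time_delayed)
    it_paths <- paste(rec$path_prefix, "costs",
                      c("incurrence_time_early", "incurrence_time_delayed"),
                      sep = "/")
    bad_ite <- ite < 0 | ite > t_de
    bad_itd <- itd < 0 | itd > t_de
    note_violation(bad_ite, it_paths[[1L]])
    note_violation(bad_itd, it_paths[[2L]])
    ok <- ok & !(bad_ite | bad_itd)

    disc_e <- (1 + rate)^(-ite)
    disc_d <- (1 + rate)^(-itd)
    cf <- if (rec$scenario == "lifesaving") 0 else 1
    cost_delta <- function(field_e, field_d) {
      ce <- field_vec(rec, "costs", field_e, rec$cs[[field_e]])
      cd <- field_vec(rec, "costs", field_d, rec$cs[[field_d]])
      bad <- ce < 0 | cd < 0
      note_violation(bad, paste(rec$path_prefix, "costs", field_e,
                                sep = "/"))
      ok <<- ok & !bad
      ce * disc_e - cf * cd * disc_d
    }
    d_dir <- cost_delta("direct_early", "direct_delayed")
    d_ip <- cost_delta("indirect_patient_early", "indirect_patient_delayed")
    d_ic <- cost_delta("indirect_caregiver_early",
                       "indirect_caregiver_delayed")
    list(q = q, d_dir = d_dir, d_ip = d_ip, d_ic = d_ic, ok = ok)
  }

  for (co in cohort_recs) {
    co_q <- numeric(n)
    co_dir <- numeric(n)
    co_ip <- numeric(n)
    co_ic <- numeric(n)
    for (rec in co) {
      ev <- eval_subgroup_draws(rec)
      feasible <- feasible & ev$ok
      co_q <- co_q + ev$q * rec$n
      co_dir <- co_dir + ev$d_dir * rec$n
      co_ip <- co_ip + ev$d_ip * rec$n
      co_ic <- co_ic + ev$d_ic * rec$n
    }
    dq <- dq + co_q
    dc_dir <- dc_dir + co_dir
    dc_ip <- dc_ip + co_ip
    dc_ic <- dc_ic + co_ic
  }
  list(delta_qalys = dq, delta_direct = dc_dir,
       delta_societal = dc_dir + dc_ip + dc_ic,
       feasible = feasible, violations = violations)
}

#' Run a probabilistic sensitivity analysis
#'
#' Identical `(seed, n_draws, dists)` reproduce bit-identical draw
#' sequences; the caller's RNG state is left untouched. If more than half
#' of all sampled draws are structurally infeasible the analysis aborts,
#' naming the parameter implicated most often.
#'
#' @param run a [model_run()].
#' @param dists named list of [distribution_spec()]s keyed by parameter
#'   path; default [default_psa_distributions()].
#' @param n_draws number of Monte Carlo draws (default 5000).
#' @param seed RNG seed.
#' @return An object of class `psa_result`: `draws` (data frame with one
#'   row per draw: `draw`, `delta_qalys`, `delta_cost_societal`,
#'   `delta_cost_payer`, `nmb`), summary means, `icer_at_means` (ratio of
#'   mean incremental cost to mean incremental QALYs), `fraction_ce` at the
#'   configured WTP, and the rejected-draw count.
#' @export
run_psa <- function(run, dists = default_psa_distributions(run),
                    n_draws = 5000L, seed = 1L) {
  stopifnot(inherits(run, "model_run"), n_draws >= 1)
  if (length(dists) > 0 && is.null(names(dists))) {
    stop("run_psa: dists must be a named list keyed by parameter path",
         call. = FALSE)
  }
  for (path in names(dists)) {
    get_parameter(run, path)      # every sampled path must resolve
    moment_match(dists[[path]])   # and have feasible moments
  }
  recs <- flatten_run(run)
  rate <- run$discount$annual_rate
  wtp <- run$economy$wtp_threshold

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)

  out_dq <- numeric(n_draws)
  out_dc <- numeric(n_draws)
  out_dd <- numeric(n_draws)
  pending <- seq_len(n_draws)
  n_sampled <- 0L
  n_rejected <- 0L
  violation_tally <- integer(0)
  round <- 0L
  while (length(pending) > 0L) {
    round <- round + 1L
    if (round > 1000L) {
      stop("run_psa: rejection sampling failed to converge", call. = FALSE)
    }
    k <- length(pending)
    samples <- lapply(dists, sample_distribution, n = k)
    ev <- evaluate_draws(recs, samples, k, rate)
    for (nm in names(ev$violations)) {
      violation_tally[nm] <- (if (nm %in% names(violation_tally)) {
        violation_tally[[nm]]
      } else 0L) + ev$violations[[nm]]
    }
    n_sampled <- n_sampled + k
    n_rejected <- n_rejected + sum(!ev$feasible)
    keep <- which(ev$feasible)
    idx <- pending[keep]
    out_dq[idx] <- ev$delta_qalys[keep]
    out_dc[idx] <- ev$delta_societal[keep]
    out_dd[idx] <- ev$delta_direct[keep]
    pending <- pending[!ev$feasible]
    if (n_rejected / n_sampled > 0.5 && n_sampled >= n_draws) {
      worst <- names(violation_tally)[which.max(violation_tally)]
      stop(sprintf(
        "run_psa: rejection rate %.0f%% exceeds 50%%; worst parameter: %s",
        100 * n_rejected / n_sampled, worst), call. = FALSE)
    }
  }

  draws <- data.frame(draw = seq_len(n_draws), delta_qalys = out_dq,
                      delta_cost_societal = out_dc,
                      delta_cost_payer = out_dd,
                      nmb = out_dq * wtp - out_dc)
  mean_dq <- mean(out_dq)
  mean_dc <- mean(out_dc)
  structure(list(
    n_draws = as.integer(n_draws), seed = as.integer(seed), draws = draws,
    mean_delta_qalys = mean_dq, mean_delta_cost_societal = mean_dc,
    icer_at_means = if (mean_dq != 0) mean_dc / mean_dq else NA_real_,
    fraction_ce = mean(out_dq > 0 & out_dc <= wtp * out_dq),
    wtp = wtp, n_rejected = as.integer(n_rejected)),
    class = "psa_result")
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' For each WTP value, the fraction of draws with a positive QALY increment
#' whose incremental cost does not exceed `wtp * delta_qalys` (the same
#' decision rule as [classify_cost_effectiveness()], applied per draw over
#' the same draw set, hence monotone in WTP).
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid vector of WTP thresholds.
#' @return Data frame with columns `wtp` and `fraction_ce`.
#' @export
psa_ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"), is.numeric(wtp_grid))
  dq <- psa$draws$delta_qalys
  dc <- psa$draws$delta_cost_societal
  frac <- vapply(wtp_grid, function(w) mean(dq > 0 & dc <= w * dq),
                 numeric(1))
  data.frame(wtp = wtp_grid, fraction_ce = frac)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d draws (seed %d, %d rejected)>\n",
              x$n_draws, x$seed, x$n_rejected))
  cat(sprintf("  mean delta QALYs: %.2f | mean societal delta cost: %.0f\n",
              x$mean_delta_qalys, x$mean_delta_cost_societal))
  cat(sprintf("  ICER at means: %.0f | fraction CE at WTP %.0f: %.3f\n",
              x$icer_at_means, x$wtp, x$fraction_ce))
  invisible(x)
}
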