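# Independent numerical oracles, deliberately implemented without touching
# the package's closed forms.

# adaptive quadrature of the discount factor over [t0, t1]
quad_exposure <- function(t0, t1, rate) {
  if (t1 == t0) return(0)
  stats::integrate(function(t) (1 + rate)^(-t), t0, t1,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

# midpoint Riemann integration of a constant utility gap times the
# discount factor over one segment
riemann_segment <- function(gap, t0, t1, rate, h = 1e-3) {
  if (t1 <= t0 || gap == 0) return(0)
  n <- ceiling((t1 - t0) / h)
  ts <- t0 + (seq_len(n) - 0.5) * (t1 - t0) / n
  sum(gap * (1 + rate)^(-ts)) * (t1 - t0) / n
}

# fine-grid integration of the piecewise utility-difference curve for a
# whole scenario (the curve is flat within segments, so per-segment
# integration is exact piecewise handling)
riemann_scenario <- function(scenario, u, tl, rate, h = 1e-3) {
  switch(scenario,
    reduced_wait =
      riemann_segment(u$u_post_early - u$u_wait,
                      tl$t_early, tl$t_delayed, rate, h) +
      riemann_segment(u$u_post_early - u$u_post_delayed,
                      tl$t_delayed, tl$t_death_counterfactual, rate, h) +
      riemann_segment(u$u_post_early,
                      tl$t_death_counterfactual, tl$t_death_early, rate, h),
    missed_surgery =
      riemann_segment(u$u_post_early - u$u_missed,
                      tl$t_early, tl$t_death_counterfactual, rate, h) +
      riemann_segment(u$u_post_early,
                      tl$t_death_counterfactual, tl$t_death_early, rate, h),
    lifesaving =
      riemann_segment(u$u_post_early, tl$t_early, tl$t_death_early,
                      rate, h))
}

# random valid scenario parameters with comfortably positive utility gaps
# (relative-error comparisons need totals bounded away from zero)
random_scenario_params <- function(scenario) {
  u_pe <- runif(1, 0.55, 0.95)
  t_e <- runif(1, 0, 0.5)
  if (scenario == "reduced_wait") {
    t_d <- t_e + runif(1, 0.1, 3)
    t_dc <- t_d + runif(1, 1, 35)
    t_de <- t_dc + runif(1, 0, 5)
    u <- utility_profile(u_wait = runif(1, 0.2, u_pe - 0.1),
                         u_post_early = u_pe,
                         u_post_delayed = runif(1, 0.3, u_pe))
    tl <- timeline(t_e, t_d, t_dc, t_de)
  } else if (scenario == "missed_surgery") {
    t_dc <- t_e + runif(1, 1, 35)
    t_de <- t_dc + runif(1, 0, 5)
    u <- utility_profile(u_post_early = u_pe,
                         u_missed = runif(1, 0.2, u_pe - 0.1))
    tl <- timeline(t_e, t_dc, t_dc, t_de)
  } else {
    t_de <- t_e + runif(1, 5, 40)
    u <- utility_profile(u_post_early = u_pe)
    tl <- timeline(t_e, t_e, t_e, t_de)
  }
  list(u = u, tl = tl)
}

rel_err <- function(got, want) abs(got - want) / abs(want)
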