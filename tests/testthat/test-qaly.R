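disc <- discount_settings(0.035)

test_that("identical arms yield zero incremental QALYs", {
  u <- utility_profile(u_wait = 0.7, u_post_early = 0.7,
                       u_post_delayed = 0.7)
  tl <- timeline(0, 1, 20, 20)
  expect_equal(qalys_reduced_wait(u, tl, disc)$total, 0)

  u2 <- utility_profile(u_post_early = 0.7, u_missed = 0.7)
  expect_equal(qalys_missed_surgery(u2, timeline(0, 20, 20, 20),
                                    disc)$total, 0)
  u3 <- utility_profile(u_post_early = 0.8)
  expect_equal(qalys_lifesaving(u3, timeline(1, 1, 1, 1), disc)$total, 0)
})

test_that("an empty waiting-time gap zeroes segment A only", {
  u <- utility_profile(u_wait = 0.5, u_post_early = 0.8,
                       u_post_delayed = 0.75)
  bd <- qalys_reduced_wait(u, timeline(1, 1, 20, 22), disc)
  expect_equal(bd$segments[["A"]], 0)
  expect_gt(bd$segments[["B"]], 0)
  expect_gt(bd$segments[["C"]], 0)
})

test_that("reduced-wait worked example matches the fine-grid oracle", {
  u <- utility_profile(u_wait = 0.5, u_post_early = 0.8,
                       u_post_delayed = 0.75)
  tl <- timeline(0, 1, 20, 22)
  got <- qalys_reduced_wait(u, tl, disc)$total
  # frozen dt = 1e-4 midpoint Riemann value of the piecewise curve
  expect_equal(got, 1.7458001231, tolerance = 1e-5)
  expect_lt(rel_err(got, riemann_scenario("reduced_wait", u, tl, 0.035,
                                          h = 1e-4)), 1e-5)
})

test_that("lifesaving scenario is the survival-gap rectangle", {
  u <- utility_profile(u_post_early = 0.8)
  expect_equal(qalys_lifesaving(u, timeline(0, 0, 0, 30),
                                discount_settings(0))$total, 24)
  tl <- timeline(0.5, 0.5, 0.5, 30)
  got <- qalys_lifesaving(u, tl, disc)$total
  expect_lt(rel_err(got, 0.8 * quad_exposure(0.5, 30, 0.035)), 1e-8)
})

test_that("missed-surgery W segment is the pure survival-gap term", {
  u <- utility_profile(u_post_early = 0.8, u_missed = 0.8)
  bd <- qalys_missed_surgery(u, timeline(0, 10, 10, 14), disc)
  expect_equal(bd$segments[["V"]], 0)
  expect_equal(bd$segments[["W"]],
               0.8 * discounted_exposure(10, 14, 0.035))
})

test_that("missed surgery equals reduced wait with segment B collapsed", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_scenario_params("missed_surgery")
    got <- qalys_missed_surgery(p$u, p$tl, disc)$total
    u_eq <- utility_profile(u_wait = p$u$u_missed,
                            u_post_early = p$u$u_post_early,
                            u_post_delayed = p$u$u_post_early)
    want <- qalys_reduced_wait(u_eq, p$tl, disc)$total
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("scenario totals carry required-utility validation", {
  tl <- timeline(0, 1, 20, 22)
  u <- utility_profile(u_post_early = 0.8)
  expect_error(qalys_reduced_wait(u, tl, disc), "u_wait")
  expect_error(qalys_missed_surgery(u, tl, disc), "u_missed")
  expect_error(qalys_lifesaving(u, tl, disc), "coincides")
})

test_that("totals are non-increasing in the discount rate", {
  u <- utility_profile(u_wait = 0.4, u_post_early = 0.85,
                       u_post_delayed = 0.7)
  tl <- timeline(0.2, 1.5, 18, 25)
  rates <- seq(0, 0.2, by = 0.02)
  totals <- vapply(rates, function(r) {
    qalys_reduced_wait(u, tl, discount_settings(r))$total
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("segment totals are invariant to interior interval splits", {
  u <- utility_profile(u_wait = 0.4, u_post_early = 0.85,
                       u_post_delayed = 0.7)
  tl <- timeline(0.2, 1.5, 18, 25)
  whole <- qalys_reduced_wait(u, tl, disc)$total
  set.seed(7)
  for (i in 1:20) {
    cut <- runif(1, tl$t_delayed, tl$t_death_counterfactual)
    left <- qalys_reduced_wait(u, timeline(0.2, 1.5, cut, cut), disc)$total
    u_right <- utility_profile(u_wait = u$u_post_delayed,
                               u_post_early = u$u_post_early,
                               u_post_delayed = u$u_post_delayed)
    right <- qalys_reduced_wait(
      u_right, timeline(cut, cut, tl$t_death_counterfactual,
                        tl$t_death_early), disc)$total
    expect_equal(left + right, whole, tolerance = 1e-12)
  }
})

test_that("subgroup dispatch scales linearly with patient counts", {
  sg0 <- make_rwt_subgroup(n = 0)
  expect_equal(subgroup_qalys(sg0, disc)$population, 0)
  sg1 <- make_rwt_subgroup(n = 1)
  sg2 <- make_rwt_subgroup(n = 2)
  expect_equal(subgroup_qalys(sg2, disc)$population,
               2 * subgroup_qalys(sg1, disc)$population)
  expect_equal(subgroup_qalys(sg1, disc)$per_patient,
               qalys_reduced_wait(sg1$utilities, sg1$timeline, disc)$total)
})

test_that("breakdown totals equal the sum of their segments", {
  set.seed(11)
  for (scenario in c("reduced_wait", "missed_surgery", "lifesaving")) {
    for (i in 1:30) {
      p <- random_scenario_params(scenario)
      bd <- switch(scenario,
        reduced_wait = qalys_reduced_wait(p$u, p$tl, disc),
        missed_surgery = qalys_missed_surgery(p$u, p$tl, disc),
        lifesaving = qalys_lifesaving(p$u, p$tl, disc))
      expect_lt(abs(bd$total - sum(bd$segments)) / max(abs(bd$total), 1e-12),
                1e-9)
    }
  }
})
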