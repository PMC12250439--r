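econ <- economy_settings(56000, 56000)

test_that("ICER reproduces the published composite worked example", {
  ic <- compute_icer(2264156090, 48385)
  expect_equal(round(ic$value), 46795)
  expect_equal(ic$flag, "none")
})

test_that("ICER markers encode degenerate quadrants without exceptions", {
  expect_equal(compute_icer(-5, 10)$flag, "dominant")
  expect_equal(compute_icer(100, -10)$flag, "dominated")
  ic <- compute_icer(100, 0)
  expect_equal(ic$flag, "undefined")
  expect_true(is.na(ic$value))
})

test_that("BCR follows the published formula", {
  expect_equal(compute_bcr(10, 56000, 280000)$value, 2)
  expect_equal(compute_bcr(0, 56000, 280000)$value, 0)
  neg <- compute_bcr(10, 56000, -280000)
  expect_equal(neg$flag, "cost_saving")
  expect_equal(neg$value, -2)
  expect_equal(compute_bcr(10, 56000, 0)$flag, "undefined")
  set.seed(33)
  for (i in 1:100) {
    dq <- runif(1, -100, 100)
    gdp <- runif(1, 1000, 1e5)
    dc <- runif(1, 1, 1e7) * sample(c(-1, 1), 1)
    expect_equal(compute_bcr(dq, gdp, dc)$value, dq * gdp / dc)
  }
})

test_that("composite aggregation uses population sums, never ICER means", {
  mk <- function(cost, qalys, n = 10) {
    # one lifesaving subgroup gives exact control of (cost, qalys)
    u <- utility_profile(u_post_early = 1)
    tl <- timeline(0, 0, 0, qalys / n)
    sg <- subgroup_parameters("MA", n, u, tl,
                              cost_set(direct_early = cost / n))
    sg
  }
  run <- model_run(
    list(surgery_cohort("a", list(mk(100, 10))),
         surgery_cohort("b", list(mk(300, 10)))),
    discount_settings(0), econ)
  res <- evaluate_model_run(run)
  expect_equal(res$cohorts$a$icer_societal$value, 10)
  expect_equal(res$cohorts$b$icer_societal$value, 30)
  expect_equal(res$composite$icer_societal$value, 20)

  solo <- evaluate_model_run(
    model_run(list(surgery_cohort("a", list(mk(100, 10)))),
              discount_settings(0), econ))
  expect_equal(solo$composite, solo$cohorts$a)
  expect_equal(aggregate_outcomes(run, res$cohorts), res$composite)
  expect_error(aggregate_outcomes(run, list()), "empty")
})

test_that("composite ICER lies within the per-cohort range", {
  set.seed(21)
  for (i in 1:25) {
    run <- generate_fixture("randomized", seed = i, n_cohorts = 3)
    res <- evaluate_model_run(run)
    qs <- vapply(res$cohorts, `[[`, numeric(1), "total_delta_qalys")
    if (any(qs <= 0)) next
    icers <- vapply(res$cohorts, function(o) o$icer_societal$value,
                    numeric(1))
    expect_gte(res$composite$icer_societal$value, min(icers) - 1e-9)
    expect_lte(res$composite$icer_societal$value, max(icers) + 1e-9)
  }
})

test_that("uniform scaling of patient counts leaves ratios unchanged", {
  run <- generate_fixture("egypt_like")
  res <- evaluate_model_run(run)
  doc <- model_run_to_list(run)
  for (i in seq_along(doc$cohorts)) {
    for (j in seq_along(doc$cohorts[[i]]$subgroups)) {
      doc$cohorts[[i]]$subgroups[[j]]$n_patients <-
        doc$cohorts[[i]]$subgroups[[j]]$n_patients * 3.7
    }
  }
  scaled <- evaluate_model_run(model_run_from_list(doc))
  expect_equal(scaled$composite$icer_societal$value,
               res$composite$icer_societal$value, tolerance = 1e-12)
  expect_equal(scaled$composite$bcr_societal$value,
               res$composite$bcr_societal$value, tolerance = 1e-12)
})

test_that("payer ICER exceeds societal exactly when indirects are savings", {
  run <- generate_fixture("egypt_like")
  for (o in evaluate_model_run(run)$cohorts) {
    indirect <- o$delta_indirect_patient + o$delta_indirect_caregiver
    if (o$total_delta_qalys > 0) {
      expect_equal(o$icer_payer$value > o$icer_societal$value,
                   indirect < 0)
    }
  }
})

test_that("cost-effectiveness classification honours the boundary", {
  mk_outcome <- function(dq, dc) {
    outcome_set(dq, waitcea:::cost_breakdown(dc, 0, 0), econ)
  }
  expect_true(classify_cost_effectiveness(mk_outcome(1, 46795), 56000))
  expect_true(classify_cost_effectiveness(mk_outcome(1, 56000), 56000))
  expect_false(classify_cost_effectiveness(mk_outcome(1, 56001), 56000))
  expect_false(classify_cost_effectiveness(mk_outcome(-1, 100), 56000))
  expect_true(classify_cost_effectiveness(mk_outcome(1, -100), 56000))
})
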