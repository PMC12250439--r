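test_that("moment matching recovers target moments", {
  # degenerate spread collapses to a point mass for any family
  expect_equal(sample_distribution(distribution_spec("beta", 0.5, 0), 10),
               rep(0.5, 10))
  p <- moment_match(distribution_spec("beta", 0.3, 0.1))
  expect_equal(p$shape1 / (p$shape1 + p$shape2), 0.3)
  g <- moment_match(distribution_spec("gamma", 100, 20))
  expect_equal(g$shape * g$scale, 100)
  expect_equal(sqrt(g$shape) * g$scale, 20)
  set.seed(8)
  draws <- sample_distribution(distribution_spec("gamma", 100, 20), 1e5)
  expect_lt(abs(mean(draws) - 100), 3 * 20 / sqrt(1e5))
  expect_lt(abs(sd(draws) - 20), 3 * 20 / sqrt(2 * 1e5))
})

test_that("infeasible beta moments raise a named validation error", {
  expect_error(moment_match(distribution_spec("beta", 0.5, 0.6,
                                              label = "u_wait")),
               "u_wait")
  expect_error(moment_match(distribution_spec("beta", 1.2, 0.1)), "\\(0, 1\\)")
  expect_error(moment_match(distribution_spec("gamma", -5, 1)), "> 0")
})

test_that("zero spreads reproduce the deterministic base case exactly", {
  run <- generate_fixture("egypt_like")
  base <- evaluate_model_run(run)$composite
  psa <- run_psa(run, default_psa_distributions(run, spread_frac = 0),
                 n_draws = 200, seed = 3)
  expect_equal(psa$n_rejected, 0L)
  expect_identical(unique(psa$draws$delta_qalys),
                   base$total_delta_qalys)
  expect_identical(unique(psa$draws$delta_cost_societal),
                   base$delta_total_societal)
  expect_identical(unique(psa$draws$delta_cost_payer),
                   base$delta_total_payer)
})

test_that("the same seed reproduces bit-identical results", {
  run <- generate_fixture("egypt_like")
  a <- run_psa(run, n_draws = 100, seed = 42)
  b <- run_psa(run, n_draws = 100, seed = 42)
  expect_identical(a$draws, b$draws)
  c <- run_psa(run, n_draws = 100, seed = 43)
  expect_false(identical(a$draws, c$draws))
})

test_that("PSA leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  run <- tiny_run()
  invisible(run_psa(run, n_draws = 10, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("draw-level means track the deterministic base case", {
  run <- generate_fixture("egypt_like")
  base <- evaluate_model_run(run)$composite
  psa <- run_psa(run, default_psa_distributions(run, spread_frac = 0.02),
                 n_draws = 5000, seed = 11)
  se <- sd(psa$draws$delta_qalys) / sqrt(psa$n_draws)
  expect_lt(abs(psa$mean_delta_qalys - base$total_delta_qalys), 3 * se)
})

test_that("the acceptability curve is monotone over the same draws", {
  run <- generate_fixture("egypt_like")
  psa <- run_psa(run, n_draws = 500, seed = 2)
  ceac <- psa_ceac(psa, seq(0, 150000, by = 5000))
  expect_true(all(diff(ceac$fraction_ce) >= 0))
  expect_equal(psa_ceac(psa, psa$wtp)$fraction_ce, psa$fraction_ce)
})

test_that("excessive rejection aborts with a parameter diagnostic", {
  run <- tiny_run(list(make_rwt_subgroup(t_early = 0, t_delayed = 1,
                                         t_death_counterfactual = 2)))
  # a grossly mis-specified delayed-surgery time lands before the early
  # surgery on almost every draw
  dists <- list("surgery_a/RWT/timeline/t_delayed" =
                  distribution_spec("normal", -5, 2))
  expect_error(run_psa(run, dists, n_draws = 50, seed = 1),
               "rejection rate.*t_delayed")
})

test_that("rejected draws are redrawn and counted", {
  run <- tiny_run(list(make_rwt_subgroup(t_early = 0.5, t_delayed = 2,
                                         t_death_counterfactual = 20)))
  dists <- list("surgery_a/RWT/timeline/t_delayed" =
                  distribution_spec("normal", 2, 0.8))
  psa <- run_psa(run, dists, n_draws = 400, seed = 6)
  expect_gt(psa$n_rejected, 0L)
  expect_equal(nrow(psa$draws), 400L)
  expect_true(all(is.finite(psa$draws$delta_qalys)))
})

test_that("unresolvable sampling paths fail fast", {
  run <- tiny_run()
  expect_error(
    run_psa(run, list("surgery_a/RWT/costs/bogus" =
                        distribution_spec("gamma", 10, 1)),
            n_draws = 10),
    "no field")
})
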