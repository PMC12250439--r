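test_that("fixture generation is deterministic under a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  generate_fixture("randomized", seed = 12, n_cohorts = 3, path = p1)
  generate_fixture("randomized", seed = 12, n_cohorts = 3, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  p3 <- withr::local_tempfile(fileext = ".yaml")
  generate_fixture("randomized", seed = 13, n_cohorts = 3, path = p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("every generated fixture loads cleanly and warning-free", {
  for (seed in 1:100) {
    run <- generate_fixture("randomized", seed = seed,
                            n_cohorts = 1 + seed %% 3)
    expect_s3_class(run, "model_run")
    expect_length(validate_model_run(run), 0L)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model_run(run, path)
    expect_no_error(load_model_run(path))
  }
})

test_that("the five-surgery fixture shows the expected qualitative pattern", {
  run <- generate_fixture("egypt_like")
  res <- evaluate_model_run(run)
  wtp <- run$economy$wtp_threshold
  cochlear <- res$cohorts$cochlear_implantation
  expect_equal(cochlear$dominance_flag, "dominant")
  expect_true(cochlear$cost_effective_at_wtp)
  retinal <- res$cohorts$retinal_surgery
  expect_gt(retinal$icer_societal$value, wtp)
  expect_false(retinal$cost_effective_at_wtp)
  for (nm in c("open_heart_surgery", "cardiac_catheterization")) {
    expect_lt(res$cohorts[[nm]]$icer_societal$value, wtp)
    expect_true(res$cohorts[[nm]]$cost_effective_at_wtp)
  }
  expect_true(res$composite$cost_effective_at_wtp)
})

test_that("calibration reproduces targets through the full pipeline", {
  run <- generate_calibrated_fixture(10, 200)
  res <- evaluate_model_run(run)
  expect_equal(res$composite$icer_societal$value, 20, tolerance = 1e-6)
  expect_equal(res$composite$total_delta_qalys, 10, tolerance = 1e-6)
  expect_equal(res$composite$delta_total_societal, 200, tolerance = 1e-4)
})

test_that("unreachable calibration targets raise instead of clamping", {
  # a huge QALY target with a strongly negative cost target would need a
  # negative direct cost on the knob
  expect_error(generate_calibrated_fixture(1e6, -1e12), "unreachable")
})

test_that("expenditure samples are seeded and match analytic moments", {
  expect_error(generate_expenditure_sample(10, 1, 0), "positive")
  a <- generate_expenditure_sample(10, 0.5, 1000, seed = 2)
  b <- generate_expenditure_sample(10, 0.5, 1000, seed = 2)
  expect_identical(a, b)
  n <- 1e5
  x <- generate_expenditure_sample(10, 0.5, n, seed = 3)
  m <- exp(10 + 0.5^2 / 2)
  s <- sqrt((exp(0.5^2) - 1) * exp(2 * 10 + 0.5^2))
  expect_lt(abs(mean(x) - m), 3 * s / sqrt(n))
  path <- withr::local_tempfile(fileext = ".txt")
  generate_expenditure_sample(10, 0.5, 50, seed = 4, path = path)
  dist <- read_expenditure_file(path)
  expect_length(dist$values, 50L)
  expect_true(all(dist$values > 0))
})
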