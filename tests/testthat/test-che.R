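test_that("catastrophic classification uses a strict boundary", {
  expect_false(is_catastrophic(0, 10000, 0.25))
  expect_true(is_catastrophic(2501, 10000, 0.25))
  expect_false(is_catastrophic(2500, 10000, 0.25))
  expect_error(is_catastrophic(100, 0, 0.25), "positive")
  expect_error(is_catastrophic(100, 1000, 1.5), "threshold")
})

test_that("a lower threshold flags a superset of households", {
  set.seed(5)
  for (i in 1:50) {
    oop <- runif(1, 0, 5e4)
    e <- runif(1, 1e3, 2e5)
    if (is_catastrophic(oop, e, 0.25)) {
      expect_true(is_catastrophic(oop, e, 0.10))
    }
  }
})

test_that("the three-household example is enumerable by hand", {
  # cutoff = 5000 / 0.25 = 20000; under the strict "exceeding" convention
  # the household spending exactly 20000 sits at, not over, the 25% share,
  # so only the 10000 household faces CHE
  dist <- expenditure_distribution(values = c(10000, 20000, 40000))
  res <- proportion_catastrophic(5000, dist, 0.25)
  expect_equal(res$proportion_catastrophic, 1 / 3)
  expect_equal(res$affordable_proportion, 2 / 3)
  expect_equal(proportion_catastrophic(5001, dist,
                                       0.25)$proportion_catastrophic, 2 / 3)
  expect_equal(proportion_catastrophic(0, dist,
                                       0.25)$proportion_catastrophic, 0)
})

test_that("lognormal CHE matches a Monte Carlo oracle", {
  dist <- expenditure_distribution(meanlog = 10.5, sdlog = 0.8)
  set.seed(99)
  draws <- rlnorm(1e6, 10.5, 0.8)
  for (oop in c(10000, 40000, 120000)) {
    p_hat <- mean(oop > 0.25 * draws)
    se <- sqrt(p_hat * (1 - p_hat) / 1e6)
    p <- proportion_catastrophic(oop, dist, 0.25)$proportion_catastrophic
    expect_lt(abs(p - p_hat), 3 * se + 1e-12)
  }
})

test_that("CHE proportion is monotone in price and threshold", {
  dist <- expenditure_distribution(meanlog = 10, sdlog = 1)
  oops <- seq(0, 2e5, length.out = 40)
  p_oop <- vapply(oops, function(o) {
    proportion_catastrophic(o, dist, 0.25)$proportion_catastrophic
  }, numeric(1))
  expect_true(all(diff(p_oop) >= 0))
  p10 <- proportion_catastrophic(30000, dist, 0.10)$proportion_catastrophic
  p25 <- proportion_catastrophic(30000, dist, 0.25)$proportion_catastrophic
  expect_gte(p10, p25)
})

test_that("empirical and parametric estimators agree at large n", {
  n <- 1e5
  vals <- generate_expenditure_sample(10.2, 0.9, n, seed = 4)
  emp <- expenditure_distribution(values = vals)
  par <- expenditure_distribution(meanlog = 10.2, sdlog = 0.9)
  for (oop in c(5000, 20000, 80000)) {
    for (th in c(0.10, 0.25)) {
      expect_lt(abs(
        proportion_catastrophic(oop, emp, th)$proportion_catastrophic -
          proportion_catastrophic(oop, par, th)$proportion_catastrophic),
        0.01)
    }
  }
})

test_that("che_table reports every intervention at every threshold", {
  dist <- expenditure_distribution(meanlog = 10, sdlog = 1)
  tab <- che_table(c(cochlear = 350000, retinal = 40000), dist)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$proportion_catastrophic + tab$affordable_proportion
                  == 1))
  cochlear <- tab[tab$intervention == "cochlear" & tab$threshold == 0.25, ]
  retinal <- tab[tab$intervention == "retinal" & tab$threshold == 0.25, ]
  expect_gt(cochlear$proportion_catastrophic,
            retinal$proportion_catastrophic)
})

test_that("expenditure files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header comment", "1000", "2500.5", ""), path)
  dist <- read_expenditure_file(path)
  expect_equal(dist$values, c(1000, 2500.5))
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("12", "oops"), bad)
  expect_error(read_expenditure_file(bad), "positive")
})
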