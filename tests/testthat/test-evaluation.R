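test_that("efficiency, bias and error metrics match worked examples", {
  s <- paired_series(c(1, 2, 3), c(1.1, 1.9, 3.2))
  expect_equal(nse(s), 1 - 0.06 / 2)
  expect_equal(rmse(s), sqrt(0.06 / 3))
  expect_equal(rrs(s), sqrt(0.06 / 3) / 1)
  perfect <- paired_series(c(1, 2, 3), c(1, 2, 3))
  expect_equal(nse(perfect), 1)
  expect_equal(rmse(perfect), 0)
  mean_model <- paired_series(c(1, 2, 3), rep(2, 3))
  expect_equal(nse(mean_model), 0)
  expect_equal(rrs(mean_model), sqrt(2 / 3))
  expect_equal(rmse(paired_series(c(0, 2), c(1, 1))), 1)
  expect_equal(rmse(paired_series(3, 0)), 3)
})

test_that("percent bias reproduces the calibration-mean identity", {
  # constant series at the calibration means: observed 0.369, predicted 0.331
  s <- paired_series(rep(0.369, 4), rep(0.331, 4))
  expect_equal(round(pbias(s), 2), 10.30)
  expect_equal(pbias(paired_series(10, 12)), -20)  # overprediction negative
  expect_equal(pbias(paired_series(1:5, 1:5)), 0)
  expect_error(pbias(paired_series(c(-1, 1), c(0, 0))), "zero")
})

test_that("R^2 is the squared Pearson correlation", {
  o <- c(1, 2, 3, 4)
  expect_equal(r_squared(paired_series(o, 2 * o + 1)), 1)
  # orthogonal after centering
  expect_equal(r_squared(paired_series(c(-1, 0, 1), c(1, -2, 1))), 0)
  expect_error(r_squared(paired_series(rep(1, 3), 1:3)), "constant")
})

test_that("rating bands are closed on the left at the printed thresholds", {
  expect_equal(rate_performance(0.707)$rating, "good")
  expect_equal(rate_performance(0.818)$rating, "excellent")
  expect_equal(rate_performance(-0.1)$rating, "not applicable")
  expect_equal(
    vapply(c(0, 0.25, 0.5, 0.75), function(E) rate_performance(E)$rating,
           character(1)),
    c("poor", "fair", "good", "excellent")
  )
  r <- rate_performance(0.9, PBIAS = 24.9, RRS = 0.71)
  expect_true(r$pbias_acceptable)
  expect_false(r$rrs_acceptable)
})

test_that("all metrics agree with naive loop oracles on random series", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    o <- rnorm(n, 10, 3)
    p <- o + rnorm(n, 0, 2)
    s <- paired_series(o, p)
    expect_lt(abs(nse(s) - oracle_nse(o, p)), 1e-12)
    expect_lt(abs(pbias(s) - oracle_pbias(o, p)), 1e-10)  # percent scale
    expect_lt(abs(rmse(s) - oracle_rmse(o, p)), 1e-12)
    expect_lt(abs(rrs(s) - oracle_rrs(o, p)), 1e-12)
    expect_lt(abs(r_squared(s) - oracle_r2(o, p)), 1e-12)
  }
})

test_that("metric identities hold on random series", {
  set.seed(5)
  for (i in 1:50) {
    o <- rnorm(8)
    p <- o + rnorm(8, 0, 0.5)
    s <- paired_series(o, p)
    n <- length(o)
    sst <- sum((o - mean(o))^2)
    expect_equal(nse(s), 1 - rmse(s)^2 * n / sst, tolerance = 1e-12)
    expect_equal(rrs(s), rmse(s) / sd(o), tolerance = 1e-12)
  }
  # underprediction gives positive bias
  expect_gt(pbias(paired_series(c(2, 3), c(1, 2))), 0)
})

test_that("the full report is internally consistent", {
  s <- paired_series(c(0.3, 0.45, 0.2, 0.5), c(0.28, 0.5, 0.25, 0.44))
  rep <- build_report(s)
  expect_equal(rep$rrs * rep$sd, rep$rmse, tolerance = 1e-12)
  expect_equal(rep$E, nse(s))
  expect_equal(rep$pbias, pbias(s))
  expect_equal(rep$mean_observed, mean(s$observed))
  perfect <- build_report(paired_series(1:5, 1:5))
  expect_equal(perfect$E, 1)
  expect_equal(perfect$pbias, 0)
  expect_equal(perfect$rrs, 0)
  expect_equal(perfect$rating, "excellent")
})

test_that("paired CSV reader enforces its schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = c("a", "b"), observed = c(1, 2),
                                  predicted = c(1.1, 2.2)), path)
  s <- read_pairs_csv(path)
  expect_named(s, c("observed", "predicted", "label"))
  readr::write_csv(tibble::tibble(x = 1), path)
  expect_error(read_pairs_csv(path), "header")
})
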