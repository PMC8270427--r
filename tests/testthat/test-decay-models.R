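test_that("noiseless exponential data is recovered exactly across k", {
  t <- 0:10
  for (k in c(0.01, 0.05, 0.2, 0.5, 1)) {
    dat <- tibble::tibble(time = t, mass = 100 * exp(-k * t))
    free <- fit_single_exponential(dat)
    forced <- fit_single_exponential(dat, force_intercept = TRUE, M0 = 100)
    expect_equal(free$k, k, tolerance = 1e-6)
    expect_equal(free$M0, 100, tolerance = 1e-4)
    expect_equal(forced$k, k, tolerance = 1e-6)
  }
})

test_that("fits flag non-decaying series and enforce minimum points", {
  dat <- tibble::tibble(time = 0:5, mass = 100 * exp(0.1 * 0:5))
  expect_warning(fit <- fit_single_exponential(dat), "not decaying")
  expect_true(fit$non_decaying)
  expect_error(fit_single_exponential(tibble::tibble(time = 0:1,
                                                     mass = c(1, 0.5))),
               "at least 3")
  expect_error(fit_power_exponential(tibble::tibble(time = 0:2,
                                                    mass = c(1, .8, .6))),
               "at least 4")
})

test_that("power-exponential fit recovers generating constants", {
  t <- 0:30
  m <- (t + 1)^0.1303 * exp(-0.1535 * t)
  fit <- fit_power_exponential(tibble::tibble(time = t, mass = m), M0 = 1)
  expect_equal(fit$k1, 0.1535, tolerance = 1e-4)
  expect_equal(fit$k2, 0.1303, tolerance = 1e-4)
})

test_that("power-exponential with k2 = 0 reduces to the exponential fit", {
  t <- 0:12
  m <- exp(-0.25 * t)
  pe <- fit_power_exponential(tibble::tibble(time = t, mass = m), M0 = 1)
  se <- fit_single_exponential(tibble::tibble(time = t, mass = m),
                               force_intercept = TRUE, M0 = 1)
  expect_equal(pe$k2, 0, tolerance = 1e-6)
  expect_equal(pe$k1, se$k, tolerance = 1e-6)
})

test_that("closed-form half-life follows -ln(0.5)/k", {
  expect_equal(half_life_exponential(0.132)$t50_years, 5.2511,
               tolerance = 1e-4)
  expect_equal(half_life_exponential(0.139)$t50_years, 4.9867,
               tolerance = 1e-4)
  expect_equal(half_life_exponential(log(2))$t50_years, 1)
  expect_error(half_life_exponential(0), "positive")
})

test_that("iterative half-life solves the dual-constant curve", {
  t50 <- half_life_power_exponential(0.1535, 0.1303)$t50_years
  expect_equal(t50, 6.2, tolerance = 0.05)
  expect_equal(t50, oracle_t50_grid(0.1535, 0.1303), tolerance = 1e-3)
  # curve value at the root is one half
  expect_equal((t50 + 1)^0.1303 * exp(-0.1535 * t50), 0.5,
               tolerance = 1e-8)
  expect_error(half_life_power_exponential(0.0001, 0.01), "cross")
})

test_that("iterative half-life reduces to the closed form when k2 = 0", {
  expect_equal(half_life_power_exponential(log(2), 0)$t50_years, 1,
               tolerance = 1e-8)
  for (k1 in c(0.05, 0.1, 0.2, 0.5, 1)) {
    expect_equal(half_life_power_exponential(k1, 0)$t50_years,
                 half_life_exponential(k1)$t50_years, tolerance = 1e-8)
  }
})

test_that("bisection agrees with the dense-grid oracle on random draws", {
  set.seed(4)
  for (i in 1:10) {
    k1 <- runif(1, 0.05, 0.5)
    k2 <- runif(1, -0.3, min(0.3, k1 * 3))
    expect_equal(half_life_power_exponential(k1, k2)$t50_years,
                 oracle_t50_grid(k1, k2), tolerance = 1e-3)
  }
})

test_that("remaining_fraction evaluates the fitted forms", {
  t <- 0:30
  pe <- fit_power_exponential(
    tibble::tibble(time = t, mass = (t + 1)^0.1303 * exp(-0.1535 * t)),
    M0 = 1
  )
  expect_equal(remaining_fraction(pe, 30), 31^0.1303 * exp(-0.1535 * 30),
               tolerance = 1e-6)
  expect_equal(remaining_fraction(pe, 30), 0.0157, tolerance = 0.01)
  expect_equal(remaining_fraction(pe, 0), 1)
  se <- fit_single_exponential(
    tibble::tibble(time = t, mass = exp(-0.139 * t))
  )
  expect_equal(remaining_fraction(se, 30), 0.0154, tolerance = 5e-3)
  expect_equal(remaining_fraction(se, 0), 1)
})

test_that("k recovery bias under multiplicative noise is below 2%", {
  set.seed(42)
  t <- 0:30
  k_true <- 0.132
  ks <- replicate(200, {
    m <- exp(-k_true * t) * exp(rnorm(31, 0, 0.05))
    fit_single_exponential(tibble::tibble(time = t, mass = m),
                           force_intercept = TRUE, M0 = 1)$k
  })
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.02)
})

test_that("tidy and glance summarise fits in broom style", {
  t <- 0:10
  fit <- fit_single_exponential(tibble::tibble(time = t,
                                               mass = exp(-0.2 * t)))
  td <- tidy(fit)
  expect_identical(td$term, c("k", "M0"))
  gl <- glance(fit)
  expect_equal(gl$t50_years, log(2) / fit$k)
  pe <- fit_power_exponential(
    tibble::tibble(time = t, mass = (t + 1)^0.1 * exp(-0.2 * t)), M0 = 1
  )
  expect_named(glance(pe),
               c("k1", "k2", "M0", "r.squared", "sse", "n", "t50_years"))
})
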