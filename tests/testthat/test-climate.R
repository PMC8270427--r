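test_that("synthetic climate is seed-deterministic", {
  site <- fixture_site("Santee")
  a <- synthesize_climate(site, 1, seed = 7)
  b <- synthesize_climate(site, 1, seed = 7)
  expect_identical(a, b)
  c <- synthesize_climate(site, 1, seed = 8)
  expect_false(identical(a$tmin_C, c$tmin_C))
})

test_that("synthetic climate recovers MAT and MAP at 30 years", {
  santee <- fixture_site("Santee")
  cl <- synthesize_climate(santee, 30, seed = 42)
  expect_gt(mean(cl$tmean_C), 18.1)
  expect_lt(mean(cl$tmean_C), 19.1)
  expect_lt(abs(sum(cl$precip_mm) / 30 - 1673.9) / 1673.9, 0.05)
  dimas <- fixture_site("San Dimas")
  cl2 <- synthesize_climate(dimas, 30, seed = 42)
  expect_lt(abs(sum(cl2$precip_mm) / 30 - 523.1) / 523.1, 0.05)
})

test_that("temperature modifier is Gaussian with optional hard threshold", {
  fungi <- guild_parameters("fungi", 0.2, t_opt_c = 25, t_sigma_c = 10)
  expect_equal(temperature_modifier(25, fungi), 1)
  expect_equal(temperature_modifier(c(15, 35), fungi),
               rep(exp(-0.5), 2))
  termites <- guild_parameters("termites", 0.2, t_opt_c = 28, t_sigma_c = 7,
                               t_threshold_c = 10)
  expect_equal(temperature_modifier(0, termites), 0)
  expect_equal(temperature_modifier(9.99, termites), 0)
  expect_gt(temperature_modifier(10.01, termites), 0)
})

test_that("moisture bucket dries monotonically and wets under rain", {
  st <- list(wood_moisture_index = 1, snowpack_mm = 0)
  idx <- numeric(50)
  for (i in 1:50) {
    st <- update_moisture(st, precip_mm = 0, tmean_C = 20, lai = 2.5)
    idx[i] <- st$wood_moisture_index
  }
  expect_true(all(diff(idx) < 0))
  expect_gt(idx[50], 0)
  st0 <- list(wood_moisture_index = 0, snowpack_mm = 0)
  wet <- update_moisture(st0, precip_mm = 50, tmean_C = 20, lai = 0)
  expect_gt(wet$wood_moisture_index, 0)
})

test_that("standing wood stays drier than downed wood", {
  set.seed(11)
  cl <- constant_climate(200)
  cl$precip_mm <- rgamma(200, 0.7, scale = 10)
  down <- moisture_series(cl, lai = 2.5, position = "downed")
  stand <- moisture_series(cl, lai = 2.5, position = "standing")
  expect_true(all(stand <= down + 1e-12))
  expect_true(all(down >= 0 & down <= 1))
})

test_that("snowfall is banked and released on melt days", {
  st <- list(wood_moisture_index = 0.2, snowpack_mm = 0)
  st <- update_moisture(st, precip_mm = 20, tmean_C = -5, lai = 0)
  expect_equal(st$snowpack_mm, 20)
  expect_equal(st$wood_moisture_index, 0.2 * (1 - 0.04 * 0.5))
  st <- update_moisture(st, precip_mm = 0, tmean_C = 4, lai = 0)
  expect_lt(st$snowpack_mm, 20)
})

test_that("moisture modifier has the stated anchors and stays in [0, 1]", {
  expect_equal(moisture_modifier(0), 0)
  expect_equal(moisture_modifier(0.6), 1)
  expect_equal(moisture_modifier(1), 0.5)
  w <- seq(0, 1, by = 0.01)
  expect_true(all(moisture_modifier(w) >= 0 & moisture_modifier(w) <= 1))
  expect_error(moisture_modifier(1.2), "\\[0, 1\\]")
})

test_that("climate reader validates, interpolates and maps Daymet headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  dates <- as.Date("2020-01-01") + 0:364
  df <- data.frame(date = dates, tmin_C = 5, tmax_C = 15, precip_mm = 2)
  readr::write_csv(df, path)
  expect_equal(nrow(read_climate_csv(path)), 365)

  bad <- df
  bad$tmin_C[10] <- 20
  readr::write_csv(bad, path)
  expect_error(read_climate_csv(path), "10")

  gap <- df[-50, ]
  readr::write_csv(gap, path)
  expect_warning(out <- read_climate_csv(path), "1 missing day")
  expect_equal(nrow(out), 365)
  expect_equal(out$tmin_C[50], 5)

  daymet <- data.frame(year = 2020, yday = 1:100,
                       check.names = FALSE)
  daymet[["tmax (deg c)"]] <- 15
  daymet[["tmin (deg c)"]] <- 5
  daymet[["prcp (mm/day)"]] <- 3
  readr::write_csv(daymet, path)
  out <- read_climate_csv(path, daymet = TRUE)
  expect_equal(out$tmean_C[1], 10)
  expect_equal(nrow(out), 100)
})
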