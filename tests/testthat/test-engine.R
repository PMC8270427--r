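const_day <- function(tmean = 25, w = 0.6) {
  list(tmean_C = tmean,
       wood_moisture_index = c(downed = w, standing = w))
}

one_cohort <- function(mass = 10) {
  cwd_cohort(tibble::tibble(position = "downed", species = 2,
                            size_class = 3, mass_Mg_ha = mass))
}

test_that("zero rates leave mass and ledger unchanged", {
  p <- flat_params(k_fungi = 0)
  st <- decomposition_state(one_cohort(), p)
  st2 <- step(st, const_day(), p)
  expect_equal(st2$cohorts$mass_C, st$cohorts$mass_C)
  expect_equal(sum(st2$ledger$cum_loss), 0)
  traj <- simulate_decomposition(one_cohort(), constant_climate(365), p, 1)
  expect_equal(traj$remaining_fraction, c(1, 1))
})

test_that("single guild under constant modifiers matches exp(-k) after one year", {
  p <- flat_params(k_fungi = 0.2)
  st <- decomposition_state(one_cohort(), p)
  for (d in 1:365) st <- step(st, const_day(tmean = 25, w = 0.6), p)
  m0 <- st$cohorts$initial_C
  expect_equal(st$cohorts$mass_C / m0, exp(-0.2), tolerance = 1e-6)
  # daily-compounding brute-force oracle
  expect_equal(st$cohorts$mass_C, oracle_daily_decay(m0, 0.2, 365),
               tolerance = 1e-12)
})

test_that("vectorised simulation reproduces the stepwise kernel", {
  set.seed(21)
  p <- random_params()
  coh <- random_cohort()
  cl <- synthesize_climate(fixture_site("Santee"), 1, seed = 5)
  forcing <- prepare_forcing(cl, lai = 2.5)
  st <- decomposition_state(coh, p)
  for (d in 1:365) {
    st <- step(st, list(
      tmean_C = forcing$tmean_C[d],
      wood_moisture_index = c(downed = forcing$windex$downed[d],
                              standing = forcing$windex$standing[d])
    ), p)
  }
  traj <- simulate_decomposition(coh, cl, p, 1, lai = 2.5,
                                 forcing = forcing)
  vec <- attr(traj, "final_state")
  expect_equal(vec$cohorts$mass_C, st$cohorts$mass_C, tolerance = 1e-10)
  expect_equal(vec$fragment_C, st$fragment_C, tolerance = 1e-10)
  expect_equal(vec$ledger$cum_loss, st$ledger$cum_loss, tolerance = 1e-10)
  expect_equal(vec$ledger$doc_produced, st$ledger$doc_produced,
               tolerance = 1e-10)
  expect_equal(vec$ledger$poc, st$ledger$poc, tolerance = 1e-10)
})

test_that("termite share of annual loss declines when resources decline", {
  p <- flat_params(k_fungi = 0.1)
  p$guilds$termites <- guild_parameters("termites", k_base = 0.3,
                                        t_opt_c = 25, t_sigma_c = 10,
                                        resource_decline = 0.5,
                                        fragmentation_share = 0.3)
  cl <- constant_climate(5 * 365)
  traj <- simulate_decomposition(one_cohort(), cl, p, 5)
  shares <- traj$share_termites[traj$year %in% 1:5]
  expect_true(all(diff(shares) < 0))
})

test_that("carbon is conserved to 1e-9 under random parameters", {
  set.seed(33)
  for (rep in 1:5) {
    p <- random_params()
    coh <- random_cohort()
    site <- fixture_site("Santee")
    cl <- synthesize_climate(site, 3, seed = rep)
    traj <- simulate_decomposition(coh, cl, p, 3, lai = 2.5)
    expect_lt(carbon_balance_residual(traj), 1e-9)
    expect_true(all(diff(traj$remaining_fraction) <= 0))
  }
})

test_that("standing cohorts decay no faster than downed ones", {
  p <- default_engine_parameters()
  cl <- synthesize_climate(fixture_site("Santee"), 5, seed = 3)
  mk <- function(pos) {
    cwd_cohort(tibble::tibble(position = pos, species = 2, size_class = 3,
                              mass_Mg_ha = 10))
  }
  down <- simulate_decomposition(mk("downed"), cl, p, 5)
  stand <- simulate_decomposition(mk("standing"), cl, p, 5)
  expect_true(all(stand$remaining_fraction >= down$remaining_fraction))
})

test_that("larger logs lose mass more slowly", {
  p <- default_engine_parameters()
  cl <- constant_climate(2 * 365)
  logs <- tibble::tibble(site = "x", position = "down", species = 2,
                         size_class = c(1, 6), diameter_cm = c(6, 40),
                         mass_kg = 100, density_g_cm3 = 0.5, length_m = 2)
  traj <- simulate_decomposition(logs, cl, p, 2)
  st <- attr(traj, "final_state")
  loss <- 1 - st$cohorts$mass_C / st$cohorts$initial_C
  expect_gt(loss[1], loss[2])
})

test_that("the horizon must be covered by the climate series", {
  p <- flat_params()
  expect_error(
    simulate_decomposition(one_cohort(), constant_climate(300), p, 1),
    "shorter"
  )
})

test_that("a one-parameter calibration recovers the target half-mass rate", {
  p <- flat_params(k_fungi = 0.05)
  cl <- constant_climate(5 * 365)
  scenario <- list(substrate = one_cohort(), climate = cl, years = 5,
                   lai = 2.5, forcing = prepare_forcing(cl, 2.5))
  res <- calibrate_defaults(
    scenario,
    targets = tibble::tibble(name = "remaining_y5", target = 0.5,
                             weight = 1),
    free = list("guilds.fungi.k_base" = c(0.01, 1)),
    base_params = p, maxit = 200, restarts = 1
  )
  traj <- simulate_decomposition(scenario$substrate, cl, res$params, 5,
                                 forcing = scenario$forcing)
  expect_equal(traj$remaining_fraction[traj$year == 5], 0.5,
               tolerance = 0.01)
})

test_that("shipped default parameters reproduce their calibration targets", {
  sc <- hugo_scenario(seed = 42)
  loss <- calibration_loss(default_engine_parameters(), sc,
                           hugo_calibration_targets())
  expect_lt(loss, 0.05)
})
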