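# Naive loop implementations used as independent oracles for the vectorised
# metrics, plus small generators for property-style tests.

oracle_nse <- function(o, p) {
  num <- 0
  den <- 0
  ob <- mean(o)
  for (i in seq_along(o)) {
    num <- num + (o[i] - p[i])^2
    den <- den + (o[i] - ob)^2
  }
  1 - num / den
}

oracle_pbias <- function(o, p) {
  num <- 0
  den <- 0
  for (i in seq_along(o)) {
    num <- num + (o[i] - p[i])
    den <- den + o[i]
  }
  100 * num / den
}

oracle_rmse <- function(o, p) {
  s <- 0
  for (i in seq_along(o)) s <- s + (o[i] - p[i])^2
  sqrt(s / length(o))
}

oracle_rrs <- function(o, p) {
  ob <- mean(o)
  s <- 0
  for (i in seq_along(o)) s <- s + (o[i] - ob)^2
  oracle_rmse(o, p) / sqrt(s / (length(o) - 1))
}

oracle_r2 <- function(o, p) {
  ob <- mean(o)
  pb <- mean(p)
  sxy <- sxx <- syy <- 0
  for (i in seq_along(o)) {
    sxy <- sxy + (o[i] - ob) * (p[i] - pb)
    sxx <- sxx + (o[i] - ob)^2
    syy <- syy + (p[i] - pb)^2
  }
  (sxy / sqrt(sxx * syy))^2
}

# Dense-grid scan for the power-exponential half-life.
oracle_t50_grid <- function(k1, k2, dt = 1e-4, tmax = 100) {
  t <- seq(0, tmax, by = dt)
  f <- (t + 1)^k2 * exp(-k1 * t)
  t[which(f <= 0.5)[1]]
}

# Daily-compounded exponential decay (brute-force engine oracle).
oracle_daily_decay <- function(m0, rate_per_year, days) {
  m <- m0
  for (d in seq_len(days)) m <- m * exp(-rate_per_year / 365)
  m
}

# A single-guild parameter set with flat responses, handy for closed-form
# checks (no lag, no decline, no size/position effects).
flat_params <- function(k_fungi = 0.2, frag = 0, doc = 0) {
  guilds <- list(
    fungi = guild_parameters("fungi", k_base = k_fungi, t_opt_c = 25,
                             t_sigma_c = 10, fragmentation_share = frag),
    termites = guild_parameters("termites", k_base = 0, t_opt_c = 28,
                                t_sigma_c = 7, t_threshold_c = 10),
    bacteria = guild_parameters("bacteria", k_base = 0, t_opt_c = 30,
                                t_sigma_c = 12),
    beetles = guild_parameters("beetles", k_base = 0, t_opt_c = 24,
                               t_sigma_c = 8, t_threshold_c = 8)
  )
  engine_parameters(guilds, size_exponent = 0, standing_multiplier = 1,
                    doc_leach_coeff = doc, poc_coeff = 2e-4,
                    forest_floor_k = 1.5)
}

# Randomised engine parameters for property tests (rates and shares drawn
# from plausible ranges).
random_params <- function() {
  g <- function(name, thr = NA) {
    guild_parameters(
      name, k_base = stats::runif(1, 0, 0.6),
      t_opt_c = stats::runif(1, 15, 32), t_sigma_c = stats::runif(1, 4, 14),
      t_threshold_c = thr,
      substrate_hardwood = stats::runif(1, 0.6, 1.4),
      substrate_softwood = stats::runif(1, 0.6, 1.4),
      colonization_lag_d = stats::runif(1, 0, 700),
      lag_shape = stats::runif(1, 0.8, 3),
      resource_decline = stats::runif(1, 0, 0.6),
      pulse_share = stats::runif(1, 0, 0.6),
      pulse_decline = stats::runif(1, 0.5, 3),
      fragmentation_share = stats::runif(1, 0, 0.5)
    )
  }
  engine_parameters(
    list(fungi = g("fungi"), termites = g("termites", 10),
         bacteria = g("bacteria"), beetles = g("beetles", 8)),
    size_exponent = stats::runif(1, 0, 0.6),
    standing_multiplier = stats::runif(1, 0.3, 1),
    doc_leach_coeff = stats::runif(1, 0, 0.05),
    poc_coeff = stats::runif(1, 0, 0.01),
    forest_floor_k = stats::runif(1, 0.2, 3),
    doc_retention = stats::runif(1, 0.5, 1)
  )
}

random_cohort <- function() {
  grid <- expand.grid(position = c("downed", "standing"), species = 1:2,
                      size_class = 1:6)
  grid$mass_Mg_ha <- stats::runif(nrow(grid), 0, 10)
  cwd_cohort(grid)
}

constant_climate <- function(days, tmean = 25, precip = 5) {
  tibble::tibble(
    date = as.Date("2001-01-01") + seq_len(days) - 1,
    tmin_C = tmean - 4, tmax_C = tmean + 4, precip_mm = precip,
    tmean_C = tmean
  )
}
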