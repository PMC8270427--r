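GUILDS <- c("fungi", "termites", "bacteria", "beetles")

#' Define a decomposer guild
#'
#' Each guild decomposes wood at a potential first-order rate `k_base`
#' (y^-1), modulated by a Gaussian temperature response (optimum `t_opt_c`,
#' width `t_sigma_c`, optional hard activity threshold `t_threshold_c`), the
#' shared wood-moisture modifier, a species-group substrate multiplier, a
#' colonization ramp and, for substrate-depleting guilds (termites,
#' beetles), an exponential decline of attack rate with substrate age.
#' A fixed share of each guild's mass loss is routed to fragments rather
#' than respired.
#'
#' @param name One of `"fungi"`, `"termites"`, `"bacteria"`, `"beetles"`.
#' @param k_base Potential rate, y^-1 (>= 0).
#' @param t_opt_c,t_sigma_c,t_threshold_c Temperature response, degrees C
#'   (`t_threshold_c = NA` for no threshold).
#' @param substrate_hardwood,substrate_softwood Dimensionless multipliers by
#'   species group.
#' @param colonization_lag_d Ramp time scale in days; activity rises as
#'   `1 - exp(-(age / lag)^lag_shape)` (0 disables the ramp).
#' @param lag_shape Weibull-type shape of the colonization ramp.
#' @param resource_decline Decline rate of the sustained attack with
#'   substrate age, y^-1.
#' @param pulse_share Fraction of the initial attack carried by a transient
#'   colonization pulse (fresh, nutrition-rich sapwood), in `[0, 1)`;
#'   relevant for termites.
#' @param pulse_decline Decay rate of that pulse, y^-1.
#' @param fragmentation_share Fraction of the guild's mass loss routed to
#'   the forest-floor fragment pool, in `[0, 1]`.
#' @return A guild parameter list.
#' @export
guild_parameters <- function(name, k_base, t_opt_c, t_sigma_c,
                             t_threshold_c = NA, substrate_hardwood = 1,
                             substrate_softwood = 1, colonization_lag_d = 0,
                             lag_shape = 1, resource_decline = 0,
                             pulse_share = 0, pulse_decline = 0,
                             fragmentation_share = 0) {
  if (!name %in% GUILDS) {
    stop("guild name must be one of: ", paste(GUILDS, collapse = ", "))
  }
  if (k_base < 0) stop("k_base must be >= 0")
  if (fragmentation_share < 0 || fragmentation_share > 1) {
    stop("fragmentation_share must lie in [0, 1]")
  }
  if (resource_decline < 0 || pulse_decline < 0) {
    stop("resource_decline and pulse_decline must be >= 0")
  }
  if (pulse_share < 0 || pulse_share >= 1) {
    stop("pulse_share must lie in [0, 1)")
  }
  list(name = name, k_base = k_base, t_opt_c = t_opt_c,
       t_sigma_c = t_sigma_c, t_threshold_c = t_threshold_c,
       substrate_hardwood = substrate_hardwood,
       substrate_softwood = substrate_softwood,
       colonization_lag_d = colonization_lag_d, lag_shape = lag_shape,
       resource_decline = resource_decline, pulse_share = pulse_share,
       pulse_decline = pulse_decline,
       fragmentation_share = fragmentation_share)
}

#' Assemble engine parameters
#'
#' @param guilds Named list with exactly the four guilds of
#'   [guild_parameters()].
#' @param size_exponent Surface-to-volume scaling: rates scale with
#'   `(d_ref_cm / diameter)^size_exponent`.
#' @param d_ref_cm Reference diameter, cm.
#' @param standing_multiplier Rate multiplier for standing wood, in `(0, 1]`.
#' @param doc_leach_coeff Fraction of decomposed carbon exported as DOC per
#'   unit wood-moisture index.
#' @param poc_coeff Fraction of fragment-pool decomposition exported as POC.
#' @param forest_floor_k First-order decay rate of the fragment pool, y^-1.
#' @param doc_retention Fraction of produced DOC retained in mineral soil.
#' @param carbon_fraction Carbon content of dry wood mass.
#' @return An object of class `engine_parameters`.
#' @export
engine_parameters <- function(guilds, size_exponent = 0.3, d_ref_cm = 10,
                              standing_multiplier = 0.6,
                              doc_leach_coeff = 0.01, poc_coeff = 2e-4,
                              forest_floor_k = 1.5, doc_retention = 0.853,
                              carbon_fraction = 0.492) {
  if (!setequal(names(guilds), GUILDS)) {
    stop("guilds must be named exactly: ", paste(GUILDS, collapse = ", "))
  }
  guilds <- guilds[GUILDS]
  fracs <- c(doc_leach_coeff, poc_coeff, doc_retention, carbon_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("doc_leach_coeff, poc_coeff, doc_retention and carbon_fraction ",
         "must lie in [0, 1]")
  }
  if (standing_multiplier <= 0 || standing_multiplier > 1) {
    stop("standing_multiplier must lie in (0, 1]")
  }
  if (size_exponent < 0 || forest_floor_k < 0 || d_ref_cm <= 0) {
    stop("size_exponent and forest_floor_k must be >= 0, d_ref_cm > 0")
  }
  structure(
    list(guilds = guilds, size_exponent = size_exponent, d_ref_cm = d_ref_cm,
         standing_multiplier = standing_multiplier,
         doc_leach_coeff = doc_leach_coeff, poc_coeff = poc_coeff,
         forest_floor_k = forest_floor_k, doc_retention = doc_retention,
         carbon_fraction = carbon_fraction),
    class = "engine_parameters"
  )
}

#' Read engine parameters from JSON
#'
#' @param path Path to a parameter JSON file with a `guilds` block and the
#'   scalar coefficients of [engine_parameters()].
#' @return An `engine_parameters` object.
#' @export
read_engine_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$guilds)) stop("parameter file lacks a 'guilds' block")
  guilds <- purrr::imap(x$guilds, function(g, nm) {
    do.call(guild_parameters, c(list(name = nm), g))
  })
  scalars <- x[setdiff(names(x), "guilds")]
  do.call(engine_parameters, c(list(guilds = guilds), scalars))
}

#' Write engine parameters to JSON
#'
#' @param params An `engine_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_engine_parameters <- function(params, path) {
  guilds <- purrr::map(params$guilds, function(g) g[setdiff(names(g), "name")])
  x <- c(list(guilds = guilds),
         params[setdiff(names(params), "guilds")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Default (calibrated) engine parameters
#'
#' The parameter file shipped with the package, the archived output of
#' [calibrate_defaults()] against the published watershed-scale blow-down
#' outputs (see the methods vignette).
#'
#' @return An `engine_parameters` object.
#' @export
default_engine_parameters <- function() {
  read_engine_parameters(
    system.file("extdata", "params_default.json", package = "cwdsim",
                mustWork = TRUE)
  )
}

# Colonization ramp and resource-decline factors at a given substrate age.
# The decline has a sustained component (resource_decline) and an optional
# transient pulse, both strictly decreasing in age when active.
guild_age_factor <- function(guild, age_days) {
  f <- rep(1, length(age_days))
  if (guild$colonization_lag_d > 0) {
    f <- f * (1 - exp(-(age_days / guild$colonization_lag_d)^guild$lag_shape))
  }
  t_y <- age_days / 365
  decline <- (1 - guild$pulse_share) * exp(-guild$resource_decline * t_y) +
    guild$pulse_share * exp(-guild$pulse_decline * t_y)
  f * decline
}

# Static per-cohort, per-guild multipliers (substrate x size x position),
# an n_cohort x 4 matrix.
static_multipliers <- function(cohorts, params) {
  n <- nrow(cohorts)
  size_f <- (params$d_ref_cm / cohorts$diameter_cm)^params$size_exponent
  pos_f <- ifelse(cohorts$position == "standing",
                  params$standing_multiplier, 1)
  out <- matrix(0, n, 4, dimnames = list(NULL, GUILDS))
  for (g in GUILDS) {
    gp <- params$guilds[[g]]
    subst <- ifelse(cohorts$species == 1L,
                    gp$substrate_hardwood, gp$substrate_softwood)
    out[, g] <- gp$k_base * subst * size_f * pos_f
  }
  out
}

#' Initialise a decomposition state
#'
#' @param substrate Either a cohort table ([cwd_cohort()]; masses in
#'   Mg ha^-1, carbon tracked in g C m^-2 using class-midpoint diameters) or
#'   a log inventory (as from [read_inventory_csv()]; masses in kg, carbon
#'   in kg C, measured diameters).
#' @param params An `engine_parameters` object.
#' @return A state list with the sub-cohort table (`cohorts`), substrate
#'   `age_days`, the fragment pool and the carbon ledger.
#' @export
decomposition_state <- function(substrate, params) {
  substrate <- tibble::as_tibble(substrate)
  if ("mass_Mg_ha" %in% names(substrate)) {
    substrate <- cwd_cohort(substrate)
    substrate <- substrate[substrate$mass_Mg_ha > 0, ]
    cohorts <- tibble::tibble(
      id = seq_len(nrow(substrate)),
      position = substrate$position,
      species = substrate$species,
      size_class = substrate$size_class,
      diameter_cm = size_class_midpoint(substrate$size_class),
      mass_C = mgha_to_gm2(substrate$mass_Mg_ha) * params$carbon_fraction
    )
    units <- "gC_m2"
  } else if ("mass_kg" %in% names(substrate)) {
    cohorts <- tibble::tibble(
      id = seq_len(nrow(substrate)),
      position = canonical_position(substrate$position),
      species = validate_species(substrate$species),
      size_class = classify_size(substrate$diameter_cm),
      diameter_cm = substrate$diameter_cm,
      mass_C = substrate$mass_kg * params$carbon_fraction
    )
    units <- "kgC"
  } else {
    stop("substrate must have either mass_Mg_ha (cohort) or mass_kg (logs)")
  }
  if (nrow(cohorts) == 0) stop("substrate is empty")
  cohorts$initial_C <- cohorts$mass_C
  list(
    cohorts = cohorts, age_days = 0, fragment_C = 0, units = units,
    ledger = list(
      initial_C = sum(cohorts$mass_C),
      resp = stats::setNames(numeric(4), GUILDS),
      resp_forest_floor = 0,
      cum_loss = stats::setNames(numeric(4), GUILDS),
      doc_produced = 0, doc_retained = 0, poc = 0
    )
  )
}

#' Advance a decomposition state by one day
#'
#' Reference single-day kernel.  Per guild the instantaneous rate is
#' `k_base * f_T * f_W * substrate * (d_ref/D)^size_exponent * position *
#' colonization * decline`; the day's mass loss
#' `M * (1 - exp(-sum(r)/365))` is apportioned across guilds in proportion
#' to their rates, split into DOC leaching, fragmentation and respiration,
#' and the fragment pool decays at `forest_floor_k`, exporting a POC share.
#' [simulate_decomposition()] runs the same arithmetic in vectorized form.
#'
#' @param state A state from [decomposition_state()].
#' @param day List with `tmean_C` and `wood_moisture_index`, the latter a
#'   named vector with entries `downed` and `standing`.
#' @param params An `engine_parameters` object.
#' @return The updated state.
#' @export
step <- function(state, day, params) {
  cohorts <- state$cohorts
  S <- static_multipliers(cohorts, params)
  age_mid <- state$age_days + 0.5
  A <- vapply(GUILDS, function(g) {
    gp <- params$guilds[[g]]
    temperature_modifier(day$tmean_C, gp) * guild_age_factor(gp, age_mid)
  }, numeric(1))
  w <- day$wood_moisture_index[cohorts$position]
  fw <- moisture_modifier(w)
  rates <- S * rep(A, each = nrow(S)) * fw   # n x 4, y^-1
  if (any(rates < 0)) stop("negative decomposition rate; check parameters")
  tot <- rowSums(rates)
  loss <- cohorts$mass_C * (1 - exp(-tot / 365))
  frac <- rates / ifelse(tot > 0, tot, 1)
  loss_g <- loss * frac                       # n x 4
  doc_g <- pmin(params$doc_leach_coeff * w, 1) * loss_g
  share <- vapply(params$guilds, `[[`, numeric(1), "fragmentation_share")
  frag_g <- (loss_g - doc_g) * rep(share, each = nrow(S))
  resp_g <- loss_g - doc_g - frag_g

  phi <- exp(-params$forest_floor_k / 365)
  ff_decay <- (1 - phi) * state$fragment_C
  poc <- params$poc_coeff * ff_decay
  led <- state$ledger
  led$cum_loss <- led$cum_loss + colSums(loss_g)
  led$resp <- led$resp + colSums(resp_g)
  led$resp_forest_floor <- led$resp_forest_floor + (ff_decay - poc)
  led$doc_produced <- led$doc_produced + sum(doc_g)
  led$doc_retained <- params$doc_retention * led$doc_produced
  led$poc <- led$poc + poc

  state$cohorts$mass_C <- cohorts$mass_C - loss
  state$fragment_C <- phi * state$fragment_C + sum(frag_g)
  state$age_days <- state$age_days + 1
  state$ledger <- led
  state
}

#' Precompute daily forcing for the engine
#'
#' Derives, once per climate series, the daily mean temperature and the
#' wood-moisture index and activity modifier for both positions.
#'
#' @param climate A validated climate tibble covering the horizon.
#' @param lai Leaf area index of the site.
#' @return A forcing list consumed by [simulate_decomposition()].
#' @export
prepare_forcing <- function(climate, lai) {
  w_down <- moisture_series(climate, lai, "downed")
  w_stand <- moisture_series(climate, lai, "standing")
  list(
    tmean_C = climate$tmean_C,
    windex = list(downed = w_down, standing = w_stand),
    fw = list(downed = moisture_modifier(w_down),
              standing = moisture_modifier(w_stand))
  )
}

#' Simulate coarse woody debris decomposition
#'
#' Runs the daily guild-partitioned decomposition model over `years` years
#' (365-day years) and aggregates annually.  Sub-cohorts (position x species
#' x size class in cohort mode, individual logs in log mode) are tracked
#' independently and summed.
#'
#' @param substrate Cohort table or log inventory, see
#'   [decomposition_state()].
#' @param climate A validated climate tibble with at least `years * 365`
#'   rows.
#' @param params An `engine_parameters` object.
#' @param years Simulation horizon in years.
#' @param lai Leaf area index driving throughfall and drying.
#' @param forcing Optional precomputed [prepare_forcing()] output.
#' @return An object of class `cwd_trajectory`: the annual trajectory tibble
#'   (years 0..`years`) with remaining fraction, carbon pools, cumulative
#'   per-guild losses and annual per-guild loss shares; attributes carry the
#'   final per-sub-cohort state and the ledger.
#' @export
simulate_decomposition <- function(substrate, climate, params, years,
                                   lai = 2.5, forcing = NULL) {
  n_days <- years * 365L
  if (nrow(climate) < n_days) {
    stop("climate series (", nrow(climate), " days) shorter than the ",
         years, "-year horizon (", n_days, " days)")
  }
  if (is.null(forcing)) forcing <- prepare_forcing(climate, lai)
  state <- decomposition_state(substrate, params)
  cohorts <- state$cohorts
  S <- static_multipliers(cohorts, params)
  if (any(S < 0)) stop("negative decomposition rate; check parameters")
  age_mid <- (seq_len(n_days) - 0.5)
  base_A <- vapply(GUILDS, function(g) {
    gp <- params$guilds[[g]]
    temperature_modifier(forcing$tmean_C[seq_len(n_days)], gp) *
      guild_age_factor(gp, age_mid)
  }, numeric(n_days))                                   # days x 4

  loss_gp <- list()   # per position: days x 4 guild losses
  doc_gp <- list()
  cwd_by_day <- matrix(0, n_days, 0)
  for (pos in unique(cohorts$position)) {
    sel <- cohorts$position == pos
    A <- base_A * forcing$fw[[pos]][seq_len(n_days)]    # days x 4
    R <- A %*% t(S[sel, , drop = FALSE])                # days x n_p
    M <- exp(-apply(R / 365, 2, cumsum))
    M <- sweep(M, 2, cohorts$mass_C[sel], `*`)          # days x n_p
    Mprev <- rbind(cohorts$mass_C[sel], M[-n_days, , drop = FALSE])
    loss_tot <- Mprev - M
    Rsafe <- ifelse(R > 0, R, 1)
    Lg <- matrix(0, n_days, 4, dimnames = list(NULL, GUILDS))
    for (gi in seq_along(GUILDS)) {
      wgt <- (loss_tot / Rsafe) *
        (A[, gi] %o% S[sel, gi, drop = TRUE]) * (R > 0)
      Lg[, gi] <- rowSums(wgt)
    }
    loss_gp[[pos]] <- Lg
    doc_gp[[pos]] <- pmin(params$doc_leach_coeff *
                            forcing$windex[[pos]][seq_len(n_days)], 1) * Lg
    cwd_by_day <- cbind(cwd_by_day, M)
    state$cohorts$mass_C[sel] <- M[n_days, ]
  }
  Lg <- Reduce(`+`, loss_gp)                            # days x 4
  doc_g <- Reduce(`+`, doc_gp)
  share <- vapply(params$guilds, `[[`, numeric(1), "fragmentation_share")
  frag_g <- sweep(Lg - doc_g, 2, share, `*`)
  resp_g <- Lg - doc_g - frag_g

  phi <- exp(-params$forest_floor_k / 365)
  frag_in <- rowSums(frag_g)
  Fpool <- as.numeric(stats::filter(frag_in, phi, method = "recursive"))
  Fprev <- c(0, Fpool[-n_days])
  ff_decay <- (1 - phi) * Fprev
  poc_d <- params$poc_coeff * ff_decay

  yr_end <- 365L * seq_len(years)
  yr_id <- rep(seq_len(years), each = 365L)
  cwd_tot <- rowSums(cwd_by_day)
  init_C <- state$ledger$initial_C
  cum_loss <- apply(Lg, 2, cumsum)
  cum_resp <- apply(resp_g, 2, cumsum)
  cum_doc <- cumsum(rowSums(doc_g))
  cum_poc <- cumsum(poc_d)
  cum_ffresp <- cumsum(ff_decay - poc_d)
  annual_loss_g <- rowsum(Lg, yr_id)                    # years x 4
  annual_tot <- rowSums(annual_loss_g)
  shares <- annual_loss_g / ifelse(annual_tot > 0, annual_tot, 1)

  traj <- tibble::tibble(
    year = 0:years,
    remaining_fraction = c(1, cwd_tot[yr_end] / init_C),
    cwd_C = c(init_C, cwd_tot[yr_end]),
    fragments_C = c(0, Fpool[yr_end]),
    doc_produced_C = c(0, cum_doc[yr_end]),
    doc_retained_C = c(0, params$doc_retention * cum_doc[yr_end]),
    poc_C = c(0, cum_poc[yr_end]),
    resp_forest_floor_C = c(0, cum_ffresp[yr_end])
  )
  for (gi in seq_along(GUILDS)) {
    traj[[paste0("cum_loss_", GUILDS[gi])]] <- c(0, cum_loss[yr_end, gi])
    traj[[paste0("resp_", GUILDS[gi], "_C")]] <- c(0, cum_resp[yr_end, gi])
    traj[[paste0("share_", GUILDS[gi])]] <- c(NA_real_, shares[, gi])
  }
  led <- state$ledger
  led$cum_loss <- cum_loss[n_days, ]
  led$resp <- cum_resp[n_days, ]
  led$resp_forest_floor <- cum_ffresp[n_days]
  led$doc_produced <- cum_doc[n_days]
  led$doc_retained <- params$doc_retention * cum_doc[n_days]
  led$poc <- cum_poc[n_days]
  state$fragment_C <- Fpool[n_days]
  state$age_days <- n_days
  state$ledger <- led

  structure(traj, class = c("cwd_trajectory", class(traj)),
            final_state = state, params = params, units = state$units)
}

#' Carbon-balance residual of a trajectory
#'
#' At every annual snapshot the initial carbon must equal the sum of the
#' remaining CWD, the fragment pool, cumulative respiration (guilds plus
#' forest floor), produced DOC and POC.
#'
#' @param traj A `cwd_trajectory`.
#' @return Maximum absolute relative residual over all snapshots.
#' @export
carbon_balance_residual <- function(traj) {
  init <- traj$cwd_C[traj$year == 0]
  resp <- rowSums(as.matrix(traj[paste0("resp_", GUILDS, "_C")]))
  tot <- traj$cwd_C + traj$fragments_C + resp + traj$resp_forest_floor_C +
    traj$doc_produced_C + traj$poc_C
  max(abs(tot - init) / init)
}

#' Cumulative guild shares of mass loss
#'
#' @param traj A `cwd_trajectory`.
#' @param through_year Year (within the horizon) at which to evaluate.
#' @return Named vector of per-guild cumulative loss fractions summing to 1.
#' @export
guild_shares <- function(traj, through_year = max(traj$year)) {
  if (!through_year %in% traj$year) {
    stop("through_year must be an annual snapshot within the horizon")
  }
  row <- traj[traj$year == through_year, paste0("cum_loss_", GUILDS)]
  cum <- stats::setNames(as.numeric(row), GUILDS)
  if (sum(cum) <= 0) stop("no mass loss through year ", through_year)
  cum / sum(cum)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a decomposition trajectory
#'
#' @param object A `cwd_trajectory`.
#' @param ... Unused.
#' @return A ggplot of remaining mass fraction over time.
#' @export
autoplot.cwd_trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$year, y = .data$remaining_fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Years since input", y = "Mass remaining (fraction)") +
    ggplot2::theme_minimal()
}

#' Write a trajectory CSV
#'
#' Emits the standard trajectory schema
#' `year,remaining_fraction,cwd_gCm2,fragments_gCm2,doc_retained_gCm2,`
#' `poc_gCm2,share_fungi,share_termites,share_bacteria,share_beetles`.
#'
#' @param traj A `cwd_trajectory` in cohort (g C m^-2) units.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- tibble::tibble(
    year = traj$year,
    remaining_fraction = traj$remaining_fraction,
    cwd_gCm2 = traj$cwd_C,
    fragments_gCm2 = traj$fragments_C,
    doc_retained_gCm2 = traj$doc_retained_C,
    poc_gCm2 = traj$poc_C,
    share_fungi = traj$share_fungi,
    share_termites = traj$share_termites,
    share_bacteria = traj$share_bacteria,
    share_beetles = traj$share_beetles
  )
  readr::write_csv(out, path)
  invisible(path)
}
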