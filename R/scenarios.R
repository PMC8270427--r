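#' Load a packaged fixture table
#'
#' Three reference tables ship with the package: `table1_sites` (the nine
#' experimental-forest site descriptors), `table2_logs` (the experimental
#' log inventory used for six-year calibration/validation runs) and
#' `table3_ws80` (the hurricane blow-down CWD cohort on watershed WS80,
#' totalling 130 Mg ha^-1).
#'
#' @param name One of `"table1_sites"`, `"table2_logs"`, `"table3_ws80"`.
#' @return A validated tibble.
#' @export
load_fixture <- function(name) {
  valid <- c("table1_sites", "table2_logs", "table3_ws80")
  if (!name %in% valid) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "cwdsim",
                      mustWork = TRUE)
  switch(name,
    table1_sites = readr::read_csv(path, show_col_types = FALSE),
    table2_logs = read_inventory_csv(path),
    table3_ws80 = read_cohort_csv(path)
  )
}

#' Site description for a fixture site
#'
#' @param site_name A site name from `table1_sites`.
#' @return A [site_description()] row.
#' @export
fixture_site <- function(site_name) {
  sites <- load_fixture("table1_sites")
  row <- sites[sites$site == site_name, ]
  if (nrow(row) != 1) {
    stop("unknown site '", site_name, "'; valid sites: ",
         paste(sites$site, collapse = ", "))
  }
  site_description(
    name = row$site, latitude_deg = row$latitude_deg,
    longitude_deg = -row$longitude_w_deg, elevation_m = row$elevation_m,
    mat_c = row$mat_c, map_mm = row$map_mm, lai = row$lai
  )
}

#' Assemble the hurricane blow-down scenario
#'
#' The 30-year watershed-scale scenario: the WS80 CWD cohort under
#' synthetic Santee climate.  The heavy forcing pre-computation is done
#' once here so repeated engine runs (e.g. during calibration) are cheap.
#'
#' @param seed Climate seed.
#' @param years Horizon in years.
#' @return A scenario list with `substrate`, `climate`, `forcing`, `years`,
#'   `lai` and `site`.
#' @export
hugo_scenario <- function(seed = 42, years = 30) {
  site <- fixture_site("Santee")
  climate <- synthesize_climate(site, years, seed)
  list(
    site = site, substrate = load_fixture("table3_ws80"), climate = climate,
    forcing = prepare_forcing(climate, site$lai), years = years,
    lai = site$lai
  )
}

run_fits <- function(traj) {
  dd <- decay_data(traj)
  list(
    exp_forced = fit_single_exponential(dd, force_intercept = TRUE, M0 = 1),
    exp_free = fit_single_exponential(dd),
    powexp = fit_power_exponential(dd, M0 = 1)
  )
}

#' Run the 30-year hurricane blow-down scenario
#'
#' Simulates decomposition of the WS80 blow-down cohort under synthetic
#' Santee climate, fits the single-exponential (both intercept modes) and
#' power-exponential curves to the annual remaining-mass series, solves the
#' half-lives, and summarises guild shares and the carbon budget.
#'
#' @param seed Climate seed.
#' @param params An `engine_parameters` object or a parameter JSON path;
#'   defaults to the shipped calibrated parameters.
#' @param years Horizon in years.
#' @return A list of class `cwd_run_report` with elements `trajectory`,
#'   `fits`, `half_lives`, `guild_shares` and `carbon_budget`.
#' @export
run_hugo <- function(seed = 42, params = NULL, years = 30) {
  params <- resolve_params(params)
  sc <- hugo_scenario(seed, years)
  traj <- simulate_decomposition(sc$substrate, sc$climate, params, years,
                                 lai = sc$lai, forcing = sc$forcing)
  fits <- run_fits(traj)
  half_lives <- dplyr::bind_rows(
    dplyr::mutate(half_life_exponential(fits$exp_forced$k),
                  model = "exponential_forced"),
    dplyr::mutate(half_life_exponential(fits$exp_free$k),
                  model = "exponential_free"),
    dplyr::mutate(half_life_power_exponential(fits$powexp$k1,
                                              fits$powexp$k2),
                  model = "power_exponential")
  )
  final <- traj[traj$year == years, ]
  budget <- tibble::tibble(
    initial_gCm2 = traj$cwd_C[traj$year == 0],
    cwd_gCm2 = final$cwd_C,
    fragments_gCm2 = final$fragments_C,
    doc_produced_gCm2 = final$doc_produced_C,
    doc_retained_gCm2 = final$doc_retained_C,
    mean_annual_doc_gCm2 = final$doc_retained_C / years,
    poc_gCm2 = final$poc_C
  )
  structure(
    list(trajectory = traj, fits = fits, half_lives = half_lives,
         guild_shares = guild_shares(traj, years), carbon_budget = budget,
         seed = seed, years = years),
    class = "cwd_run_report"
  )
}

#' Run a six-year experimental-forest log scenario
#'
#' Simulates the packaged experimental logs of one site for six years under
#' that site's synthetic climate and reports the predicted per-log mass-loss
#' fraction, the quantity compared against measured (MLML) and calculated
#' (CLML) mass loss by the evaluation module.
#'
#' @param site_name A site from `table1_sites`.
#' @param position Optional filter, `"downed"` or `"standing"`.
#' @param seed Climate seed.
#' @param params Engine parameters (default: shipped calibrated set).
#' @param years Horizon in years.
#' @return A list of class `cwd_run_report` with elements `trajectory` and
#'   `predicted` (per-log predicted loss fractions).
#' @export
run_fwde_site <- function(site_name, position = NULL, seed = 42,
                          params = NULL, years = 6) {
  params <- resolve_params(params)
  site <- fixture_site(site_name)
  logs <- load_fixture("table2_logs")
  logs <- logs[logs$site == site_name, ]
  if (!is.null(position)) {
    logs <- logs[logs$position == canonical_position(position), ]
  }
  if (nrow(logs) == 0) stop("no logs for site '", site_name, "'")
  climate <- synthesize_climate(site, years, seed)
  traj <- simulate_decomposition(logs, climate, params, years,
                                 lai = site$lai)
  st <- attr(traj, "final_state")
  predicted <- dplyr::mutate(
    st$cohorts,
    site = site_name,
    predicted_loss_fraction = 1 - .data$mass_C / .data$initial_C
  )
  predicted <- predicted[, c("site", "position", "species", "size_class",
                             "diameter_cm", "predicted_loss_fraction")]
  structure(
    list(trajectory = traj, predicted = predicted, site = site,
         seed = seed, years = years),
    class = "cwd_run_report"
  )
}

resolve_params <- function(params) {
  if (is.null(params)) return(default_engine_parameters())
  if (is.character(params)) return(read_engine_parameters(params))
  stopifnot(inherits(params, "engine_parameters"))
  params
}

#' @export
print.cwd_run_report <- function(x, ...) {
  final <- x$trajectory[x$trajectory$year == max(x$trajectory$year), ]
  cat("CWD decomposition run (", max(x$trajectory$year), " years, seed ",
      x$seed, ")\n", sep = "")
  cat("  remaining mass fraction:",
      format(final$remaining_fraction, digits = 3), "\n")
  if (!is.null(x$guild_shares)) {
    cat("  cumulative guild shares:",
        paste(names(x$guild_shares),
              format(100 * x$guild_shares, digits = 3), "%",
              collapse = ", "), "\n")
  }
  if (!is.null(x$fits)) {
    cat("  k (forced intercept):",
        format(x$fits$exp_forced$k, digits = 4), "y^-1\n")
  }
  invisible(x)
}
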