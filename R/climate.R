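#' Describe a simulation site
#'
#' Bundles the static site descriptors used to synthesize climate and to
#' drive the moisture bucket: location, mean annual temperature (MAT),
#' mean annual precipitation (MAP) and leaf area index (LAI).
#'
#' @param name Site name.
#' @param latitude_deg,longitude_deg Coordinates in decimal degrees.
#' @param elevation_m Elevation above mean sea level, m.
#' @param mat_c Mean annual temperature, degrees C.
#' @param map_mm Mean annual precipitation, mm (must be > 0).
#' @param lai Leaf area index, m^2 m^-2, in `[0, 10]`.
#' @param annual_litterfall_Mg_ha Optional annual litterfall; retained as a
#'   descriptor, not used by the shipped engine.
#' @return A one-row tibble.
#' @export
site_description <- function(name, latitude_deg, longitude_deg = NA_real_,
                             elevation_m = NA_real_, mat_c, map_mm, lai,
                             annual_litterfall_Mg_ha = NA_real_) {
  if (map_mm <= 0) stop("map_mm must be positive")
  if (lai < 0 || lai > 10) stop("lai must lie in [0, 10]")
  tibble::tibble(
    name = name, latitude_deg = latitude_deg, longitude_deg = longitude_deg,
    elevation_m = elevation_m, mat_c = mat_c, map_mm = map_mm, lai = lai,
    annual_litterfall_Mg_ha = annual_litterfall_Mg_ha
  )
}

validate_climate <- function(climate) {
  climate <- tibble::as_tibble(climate)
  need <- c("date", "tmin_C", "tmax_C", "precip_mm")
  missing_cols <- setdiff(need, names(climate))
  if (length(missing_cols)) {
    stop("climate series missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(climate$tmin_C > climate$tmax_C)
  if (length(bad)) {
    stop("tmin_C exceeds tmax_C on row(s): ", paste(utils::head(bad, 5),
                                                    collapse = ", "))
  }
  if (any(climate$precip_mm < 0)) stop("precip_mm must be >= 0")
  d <- diff(as.integer(climate$date))
  if (any(d <= 0)) stop("dates must be strictly increasing")
  if (any(d > 1)) stop("climate series has gaps after interpolation")
  climate$tmean_C <- (climate$tmin_C + climate$tmax_C) / 2
  climate
}

#' Read a daily climate CSV
#'
#' The native schema has exactly the columns `date,tmin_C,tmax_C,precip_mm`
#' with ISO dates.  Daymet-style exports (`year`, `yday`, `tmax (deg c)`,
#' `tmin (deg c)`, `prcp (mm/day)`) are accepted with `daymet = TRUE`.
#' Isolated single missing days are filled by linear interpolation (a
#' warning reports how many); longer gaps or more than 5% missing days are
#' errors, as are rows with `tmin > tmax`.
#'
#' @param path Path to the CSV file.
#' @param daymet Map Daymet export headers onto the native schema.
#' @return A validated climate tibble with an added `tmean_C` column.
#' @export
read_climate_csv <- function(path, daymet = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (daymet) {
    need <- c("year", "yday", "tmax (deg c)", "tmin (deg c)", "prcp (mm/day)")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) {
      stop("Daymet file missing columns: ",
           paste(missing_cols, collapse = ", "))
    }
    raw <- tibble::tibble(
      date = as.Date(paste0(raw$year, "-01-01")) + raw$yday - 1,
      tmin_C = raw[["tmin (deg c)"]],
      tmax_C = raw[["tmax (deg c)"]],
      precip_mm = raw[["prcp (mm/day)"]]
    )
  }
  expected <- c("date", "tmin_C", "tmax_C", "precip_mm")
  if (!all(expected %in% names(raw))) {
    stop("climate header must contain: ", paste(expected, collapse = ","))
  }
  raw <- raw[expected]
  raw$date <- as.Date(raw$date)
  if (any(is.na(raw$date))) {
    stop("unparseable date on row(s): ",
         paste(utils::head(which(is.na(raw$date)), 5), collapse = ", "))
  }
  full <- tibble::tibble(date = seq(min(raw$date), max(raw$date), by = "day"))
  n_missing <- nrow(full) - nrow(raw)
  if (n_missing > 0.05 * nrow(full)) {
    stop("more than 5% of days missing (", n_missing, " of ", nrow(full), ")")
  }
  missing_dates <- setdiff(as.integer(full$date), as.integer(raw$date))
  if (length(missing_dates)) {
    runs <- split(missing_dates, cumsum(c(1, diff(missing_dates) != 1)))
    if (any(lengths(runs) > 1)) {
      stop("climate series has gaps longer than one day; only isolated ",
           "single missing days are interpolated")
    }
    warning("interpolated ", length(missing_dates), " missing day(s)")
    out <- dplyr::left_join(full, raw, by = "date")
    for (col in c("tmin_C", "tmax_C", "precip_mm")) {
      out[[col]] <- stats::approx(seq_len(nrow(out)), out[[col]],
                                  xout = seq_len(nrow(out)))$y
    }
    raw <- out
  }
  validate_climate(raw)
}

#' Synthesize a daily climate series
#'
#' Generates a seed-reproducible stand-in for station data: daily mean
#' temperature is MAT plus a seasonal sinusoid (amplitude `0.3 * |latitude|`
#' degrees C, bounded to `[2, 16]`, peaking in mid-July) plus AR(1) noise
#' (sd 2 degrees C, lag-1 correlation 0.7), with a fixed 8 degrees C diurnal
#' range.  Precipitation uses a Bernoulli wet-day occurrence (p = 0.3) with
#' gamma-distributed wet-day amounts whose expectation reproduces MAP.
#' Years are 365 days long.
#'
#' @param site A [site_description()] row.
#' @param years Number of years (>= 1).
#' @param seed Integer seed; equal `(site, years, seed)` gives identical
#'   output.
#' @return A validated climate tibble with `tmean_C`.
#' @export
synthesize_climate <- function(site, years, seed = 42) {
  stopifnot(years >= 1)
  n <- years * 365L
  amp <- min(max(0.3 * abs(site$latitude_deg), 2), 16)
  if (is.na(amp)) amp <- 10
  doy <- rep(1:365, years)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  innov <- stats::rnorm(n, sd = 2 * sqrt(1 - 0.7^2))
  ar1 <- as.numeric(stats::filter(innov, 0.7, method = "recursive"))
  tmean <- site$mat_c + amp * cos(2 * pi * (doy - 200) / 365) + ar1
  wet <- stats::runif(n) < 0.3
  shape <- 0.7
  mean_amount <- site$map_mm / (365 * 0.3)
  amount <- stats::rgamma(n, shape = shape, scale = mean_amount / shape)
  validate_climate(tibble::tibble(
    date = as.Date("2001-01-01") + seq_len(n) - 1,
    tmin_C = tmean - 4,
    tmax_C = tmean + 4,
    precip_mm = ifelse(wet, amount, 0)
  ))
}

#' Guild temperature modifier
#'
#' Gaussian thermal response `exp(-(T - T_opt)^2 / (2 sigma^2))`, equal to 1
#' at the guild's optimum.  Guilds with a hard activity threshold (termites,
#' beetles) are fully inactive below it.
#'
#' @param tmean_C Numeric vector of daily mean temperatures.
#' @param guild A guild parameter list with `t_opt_c`, `t_sigma_c` and
#'   optionally `t_threshold_c` (`NA` for none); see [guild_parameters()].
#' @return Values in `[0, 1]`.
#' @export
temperature_modifier <- function(tmean_C, guild) {
  f <- exp(-(tmean_C - guild$t_opt_c)^2 / (2 * guild$t_sigma_c^2))
  thr <- guild$t_threshold_c
  if (!is.null(thr) && length(thr) == 1 && !is.na(thr)) {
    f[tmean_C < thr] <- 0
  }
  f
}

# Bucket constants: capacity (mm) converts throughfall to index gain;
# drying is first-order in the index with a temperature-dependent rate,
# doubled for standing wood; snow accumulates below 0 C and melts at a
# degree-day rate.
.bucket <- list(capacity_mm = 40, drying_per_day = 0.04,
                standing_drying_factor = 2, melt_mm_per_degday = 2.5)

#' Advance the wood-moisture bucket by one day
#'
#' A dimensionless bucket (index in `[0, 1]`) proxies wood water content:
#' it gains from throughfall (`precip * exp(-0.5 * LAI)`), loses by
#' first-order drying that accelerates with temperature, and standing wood
#' dries twice as fast as downed wood.  Precipitation on days at or below
#' 0 degrees C accumulates as snowpack and enters the bucket on melt days.
#'
#' @param state List with `wood_moisture_index` (in `[0, 1]`) and
#'   `snowpack_mm`.
#' @param precip_mm,tmean_C Daily forcing.
#' @param lai Leaf area index.
#' @param position `"downed"` or `"standing"`.
#' @return The updated state list.
#' @export
update_moisture <- function(state, precip_mm, tmean_C, lai,
                            position = "downed") {
  position <- canonical_position(position)
  w <- state$wood_moisture_index
  snow <- state$snowpack_mm
  if (tmean_C <= 0) {
    snow <- snow + precip_mm
    water <- 0
  } else {
    melt <- min(snow, .bucket$melt_mm_per_degday * tmean_C)
    snow <- snow - melt
    water <- precip_mm + melt
  }
  gain <- water * exp(-0.5 * lai) / .bucket$capacity_mm
  rate <- .bucket$drying_per_day * (0.5 + pmax(tmean_C, 0) / 20)
  if (position == "standing") rate <- rate * .bucket$standing_drying_factor
  w <- w * (1 - min(rate, 1)) + gain
  list(wood_moisture_index = min(max(w, 0), 1), snowpack_mm = snow)
}

#' Daily wood-moisture index over a climate series
#'
#' Runs [update_moisture()] over every day of a climate series from an
#' initial index of 0.5 with no snowpack.
#'
#' @param climate A validated climate tibble (see [read_climate_csv()]).
#' @param lai Leaf area index.
#' @param position `"downed"` or `"standing"`.
#' @return Numeric vector of daily indices in `[0, 1]`.
#' @export
moisture_series <- function(climate, lai, position = "downed") {
  position <- canonical_position(position)
  n <- nrow(climate)
  tmean <- climate$tmean_C
  precip <- climate$precip_mm
  thr_factor <- exp(-0.5 * lai) / .bucket$capacity_mm
  base <- .bucket$drying_per_day *
    (if (position == "standing") .bucket$standing_drying_factor else 1)
  out <- numeric(n)
  w <- 0.5
  snow <- 0
  for (i in seq_len(n)) {
    ti <- tmean[i]
    if (ti <= 0) {
      snow <- snow + precip[i]
      water <- 0
    } else {
      melt <- min(snow, .bucket$melt_mm_per_degday * ti)
      snow <- snow - melt
      water <- precip[i] + melt
    }
    rate <- base * (0.5 + max(ti, 0) / 20)
    w <- w * (1 - min(rate, 1)) + water * thr_factor
    if (w > 1) w <- 1 else if (w < 0) w <- 0
    out[i] <- w
  }
  out
}

#' Wood-moisture activity modifier
#'
#' Unimodal response of decomposer activity to the wood-moisture index:
#' 0 when bone dry, peaking at 1 at an index of 0.6, and declining to 0.5 at
#' saturation (waterlogging limits oxygen supply).
#'
#' @param wood_moisture_index Numeric vector in `[0, 1]`.
#' @return Values in `[0, 1]`.
#' @export
moisture_modifier <- function(wood_moisture_index) {
  w <- wood_moisture_index
  if (any(w < 0 | w > 1)) stop("wood_moisture_index must lie in [0, 1]")
  ifelse(w <= 0.6, w / 0.6, 1 - 1.25 * (w - 0.6))
}
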