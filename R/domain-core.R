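#' Coarse woody debris size classes
#'
#' The six diameter classes used throughout the package, as half-open
#' intervals `[lower_cm, upper_cm)`.  Class 1 spans 4.5--7.5 cm and class 6
#' ends at 45 cm; a boundary diameter such as 7.5 cm therefore belongs to the
#' upper class.
#'
#' @return A tibble with columns `size_class`, `lower_cm`, `upper_cm` and
#'   `midpoint_cm`.
#' @export
#' @examples
#' size_classes()
size_classes <- function() {
  lower <- c(4.5, 7.5, 15, 22.5, 30, 37.5)
  upper <- c(7.5, 15, 22.5, 30, 37.5, 45)
  tibble::tibble(
    size_class = 1:6,
    lower_cm = lower,
    upper_cm = upper,
    midpoint_cm = (lower + upper) / 2
  )
}

#' Assign diameters to size classes
#'
#' Maps log diameters onto the six half-open diameter classes of
#' [size_classes()].  Valid diameters lie in `[4.5, 45)` cm; anything outside
#' is an error.
#'
#' @param diameter_cm Numeric vector of diameters in cm.
#' @return Integer vector of size-class indices (1--6).
#' @export
#' @examples
#' classify_size(c(5.96, 7.5, 18.75))
classify_size <- function(diameter_cm) {
  stopifnot(is.numeric(diameter_cm))
  bad <- !is.finite(diameter_cm) | diameter_cm < 4.5 | diameter_cm >= 45
  if (any(bad)) {
    stop(
      "diameter(s) ", paste(diameter_cm[bad], collapse = ", "),
      " outside the valid CWD range [4.5, 45) cm"
    )
  }
  cls <- size_classes()
  idx <- findInterval(diameter_cm, cls$lower_cm)
  as.integer(cls$size_class[idx])
}

#' Midpoint diameter of a size class
#'
#' @param size_class Integer vector of class indices (1--6).
#' @return Numeric vector of class-midpoint diameters in cm.
#' @export
size_class_midpoint <- function(size_class) {
  stopifnot(all(size_class %in% 1:6))
  size_classes()$midpoint_cm[size_class]
}

canonical_position <- function(position) {
  out <- dplyr::case_match(
    tolower(as.character(position)),
    c("down", "downed") ~ "downed",
    c("stand", "standing") ~ "standing"
  )
  if (any(is.na(out))) {
    stop("position must be one of 'down(ed)' or 'stand(ing)', got: ",
         paste(unique(position[is.na(out)]), collapse = ", "))
  }
  out
}

validate_species <- function(species) {
  species <- as.integer(species)
  if (any(is.na(species)) || !all(species %in% c(1L, 2L))) {
    stop("species code must be 1 (hardwood) or 2 (softwood)")
  }
  species
}

#' Measured log mass loss (MLML)
#'
#' Field bookkeeping for whole-log reweighing: the log is weighed wet in the
#' field at the final sampling, converted to a dry-weight basis with the
#' disk-averaged moisture fraction, and compared with the initial dry weight.
#'
#' @param records Data frame with columns `initial_dry_mass_kg`,
#'   `field_weight_kg` (wet weight at final sampling) and
#'   `disk_moisture_fraction` (average of the two end disks, in `[0, 0.9]`).
#' @return The input as a tibble with an added `mlml` column: the measured
#'   mass-loss fraction, clamped to `[0, 1]` (a warning reports clamping,
#'   which arises when field data imply a small mass gain).
#' @export
#' @examples
#' measured_mass_loss(tibble::tibble(
#'   initial_dry_mass_kg = 100, field_weight_kg = 100,
#'   disk_moisture_fraction = 0.36
#' ))
measured_mass_loss <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("initial_dry_mass_kg", "field_weight_kg", "disk_moisture_fraction")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(records$initial_dry_mass_kg <= 0)) {
    stop("initial_dry_mass_kg must be positive")
  }
  if (any(records$field_weight_kg < 0)) stop("field_weight_kg must be >= 0")
  m <- records$disk_moisture_fraction
  if (any(m < 0 | m > 0.9)) {
    stop("disk_moisture_fraction must lie in [0, 0.9]")
  }
  dry_t6 <- records$field_weight_kg * (1 - m)
  loss <- (records$initial_dry_mass_kg - dry_t6) / records$initial_dry_mass_kg
  clamped <- loss < 0 | loss > 1
  if (any(clamped)) {
    warning(sum(clamped), " mass-loss fraction(s) outside [0, 1] clamped")
  }
  records$mlml <- pmin(pmax(loss, 0), 1)
  records
}

#' Calculated log mass loss (CLML)
#'
#' Density-based bookkeeping: mass loss inferred from the change in
#' disk wood density between deployment and final sampling, applied to the
#' (constant) log volume, i.e. `1 - density_t6 / density_t0`.
#'
#' @param records Data frame with columns `disk_density_t0` and
#'   `disk_density_t6` (g cm^-3).
#' @return The input as a tibble with an added `clml` column, clamped to
#'   `[0, 1]`.  A final density more than 10% above the initial density is
#'   treated as measurement noise: the loss is clamped to 0 with a warning.
#' @export
calculated_mass_loss <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("disk_density_t0", "disk_density_t6")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d0 <- records$disk_density_t0
  d6 <- records$disk_density_t6
  if (any(d0 <= 0) || any(d6 <= 0)) stop("disk densities must be positive")
  if (any(d6 > 1.1 * d0)) {
    warning("final disk density exceeds initial by more than 10%; ",
            "mass loss clamped to 0")
  }
  records$clml <- pmin(pmax(1 - d6 / d0, 0), 1)
  records
}

#' Construct a CWD cohort table
#'
#' A cohort describes standing stock of coarse woody debris per
#' (position, species, size class) cell in Mg ha^-1, the schema used for
#' watershed-scale simulations.
#'
#' @param data Data frame with columns `position` (`downed`/`standing`, the
#'   short forms `down`/`stand` are accepted), `species` (1 = hardwood,
#'   2 = softwood) and `size_class` (1--6), plus `mass_Mg_ha` (>= 0).
#' @return A validated tibble with canonical position labels.
#' @export
cwd_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("position", "species", "size_class", "mass_Mg_ha")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data$position <- canonical_position(data$position)
  data$species <- validate_species(data$species)
  if (!all(data$size_class %in% 1:6)) stop("size_class must be 1..6")
  data$size_class <- as.integer(data$size_class)
  if (any(data$mass_Mg_ha < 0)) stop("mass_Mg_ha must be >= 0")
  data
}

#' Total mass of a cohort
#'
#' @param cohort A cohort table, see [cwd_cohort()].
#' @return Total mass in Mg ha^-1.
#' @export
cohort_total <- function(cohort) {
  cohort <- cwd_cohort(cohort)
  sum(cohort$mass_Mg_ha)
}

#' Convert Mg ha^-1 to g m^-2
#'
#' @param mass_Mg_ha Numeric vector, >= 0.
#' @return Mass in g m^-2 (`mass * 100`).
#' @export
mgha_to_gm2 <- function(mass_Mg_ha) {
  stopifnot(is.numeric(mass_Mg_ha), all(mass_Mg_ha >= 0))
  mass_Mg_ha * 100
}

#' Read a log inventory CSV
#'
#' Expects exactly the columns
#' `site,position,species,size_class,diameter_cm,mass_kg,density_g_cm3,length_m`.
#' Diameters must agree with the declared size class and wood densities must
#' be physically plausible (0.05--1.2 g cm^-3).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of log specimens.
#' @export
read_inventory_csv <- function(path) {
  expected <- c("site", "position", "species", "size_class", "diameter_cm",
                "mass_kg", "density_g_cm3", "length_m")
  logs <- readr::read_csv(path, show_col_types = FALSE)
  if (!identical(names(logs), expected)) {
    stop("inventory header must be exactly: ", paste(expected, collapse = ","))
  }
  logs$position <- canonical_position(logs$position)
  logs$species <- validate_species(logs$species)
  if (any(logs$mass_kg <= 0)) stop("mass_kg must be positive")
  if (any(logs$density_g_cm3 <= 0.05 | logs$density_g_cm3 >= 1.2)) {
    stop("density_g_cm3 outside plausible range (0.05, 1.2)")
  }
  implied <- classify_size(logs$diameter_cm)
  if (!all(implied == logs$size_class)) {
    bad <- which(implied != logs$size_class)
    stop("diameter does not match declared size class on row(s): ",
         paste(bad, collapse = ", "))
  }
  logs
}

#' Read a cohort CSV
#'
#' Expects exactly the columns `position,species,size_class,mass_Mg_ha`.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort tibble, see [cwd_cohort()].
#' @export
read_cohort_csv <- function(path) {
  expected <- c("position", "species", "size_class", "mass_Mg_ha")
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  if (!identical(names(cohort), expected)) {
    stop("cohort header must be exactly: ", paste(expected, collapse = ","))
  }
  cwd_cohort(cohort)
}
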