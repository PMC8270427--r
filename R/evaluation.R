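#' Construct a paired observed/predicted series
#'
#' @param observed,predicted Numeric vectors of equal length (>= 1), finite.
#' @param labels Optional identifiers.
#' @return A tibble with columns `observed`, `predicted` and optionally
#'   `label`.
#' @export
paired_series <- function(observed, predicted, labels = NULL) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observed and predicted must be finite")
  }
  out <- tibble::tibble(observed = observed, predicted = predicted)
  if (!is.null(labels)) out$label <- labels
  out
}

check_pairs <- function(pairs, min_n = 1) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("observed", "predicted")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(pairs) < min_n) stop("need at least ", min_n, " pairs")
  if (any(!is.finite(pairs$observed)) || any(!is.finite(pairs$predicted))) {
    stop("observed and predicted must be finite")
  }
  pairs
}

#' Nash-Sutcliffe model efficiency
#'
#' `E = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`, in `(-Inf, 1]`; 1 for a
#' perfect model, 0 for a model no better than the observed mean.
#'
#' @param pairs Data frame with columns `observed` and `predicted`.
#' @return The efficiency E.
#' @export
nse <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 2)
  sst <- sum((pairs$observed - mean(pairs$observed))^2)
  if (sst == 0) stop("observed values are constant; E is undefined")
  1 - sum((pairs$observed - pairs$predicted)^2) / sst
}

#' Percent bias
#'
#' `PBIAS = 100 * sum(O - P) / sum(O)`: positive when the model
#' underpredicts the observations in aggregate.
#'
#' @inheritParams nse
#' @return Percent bias.
#' @export
pbias <- function(pairs) {
  pairs <- check_pairs(pairs)
  so <- sum(pairs$observed)
  if (so == 0) stop("sum of observed values is zero; PBIAS is undefined")
  100 * sum(pairs$observed - pairs$predicted) / so
}

#' Root mean squared error
#'
#' `sqrt(sum((O - P)^2) / n)` (population convention, divisor n).
#'
#' @inheritParams nse
#' @return RMSE in the units of the observations.
#' @export
rmse <- function(pairs) {
  pairs <- check_pairs(pairs)
  sqrt(mean((pairs$observed - pairs$predicted)^2))
}

#' RMSE to observed-standard-deviation ratio
#'
#' `RRS = RMSE / SD(observed)`, with the SD using the sample convention
#' (divisor n - 1), the standard RSR definition.
#'
#' @inheritParams nse
#' @return The dimensionless ratio.
#' @export
rrs <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 2)
  sd_o <- stats::sd(pairs$observed)
  if (sd_o == 0) stop("observed values are constant; RRS is undefined")
  rmse(pairs) / sd_o
}

#' Squared Pearson correlation of observed and predicted
#'
#' @inheritParams nse
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 2)
  if (stats::sd(pairs$observed) == 0 || stats::sd(pairs$predicted) == 0) {
    stop("R^2 is undefined for constant series")
  }
  stats::cor(pairs$observed, pairs$predicted)^2
}

#' Rate model performance
#'
#' Applies the conventional five-band efficiency rating (closed on the
#' left): E < 0 "not applicable"; [0, 0.25) "poor"; [0.25, 0.5) "fair";
#' [0.5, 0.75) "good"; E >= 0.75 "excellent".  PBIAS is acceptable within
#' (-25, 25)% and RRS within [0, 0.7].
#'
#' @param E Model efficiency.
#' @param PBIAS Percent bias (optional).
#' @param RRS RMSE/SD ratio (optional).
#' @return One-row tibble with `rating`, `pbias_acceptable` and
#'   `rrs_acceptable` (NA when the metric is not supplied).
#' @export
rate_performance <- function(E, PBIAS = NA_real_, RRS = NA_real_) {
  stopifnot(is.finite(E))
  rating <- dplyr::case_when(
    E < 0 ~ "not applicable",
    E < 0.25 ~ "poor",
    E < 0.5 ~ "fair",
    E < 0.75 ~ "good",
    TRUE ~ "excellent"
  )
  tibble::tibble(
    rating = rating,
    pbias_acceptable = if (is.na(PBIAS)) NA else PBIAS > -25 & PBIAS < 25,
    rrs_acceptable = if (is.na(RRS)) NA else RRS >= 0 & RRS <= 0.7
  )
}

#' Build a full performance report
#'
#' Computes all evaluation metrics for a paired series, in the layout used
#' to summarise calibration/validation comparisons: efficiency, R^2,
#' percent bias, RMSE, observed SD, RRS, the two means and the rating.
#'
#' @inheritParams nse
#' @return One-row tibble of class `performance_report`.
#' @export
build_report <- function(pairs) {
  pairs <- check_pairs(pairs, min_n = 2)
  E <- nse(pairs)
  PB <- pbias(pairs)
  RM <- rmse(pairs)
  SD <- stats::sd(pairs$observed)
  RR <- rrs(pairs)
  bands <- rate_performance(E, PB, RR)
  out <- tibble::tibble(
    E = E, r_squared = r_squared(pairs), pbias = PB, rmse = RM, sd = SD,
    rrs = RR, mean_observed = mean(pairs$observed),
    mean_predicted = mean(pairs$predicted), n = nrow(pairs),
    rating = bands$rating,
    pbias_acceptable = bands$pbias_acceptable,
    rrs_acceptable = bands$rrs_acceptable
  )
  class(out) <- c("performance_report", class(out))
  out
}

#' Read a paired observed/predicted CSV
#'
#' Expects exactly the columns `id,observed,predicted`.
#'
#' @param path Path to the CSV file.
#' @return A paired-series tibble with `label` carrying the ids.
#' @export
read_pairs_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!identical(names(x), c("id", "observed", "predicted"))) {
    stop("pairs header must be exactly: id,observed,predicted")
  }
  paired_series(x$observed, x$predicted, labels = x$id)
}
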