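#' Extract decay data from a trajectory
#'
#' @param traj A `cwd_trajectory`.
#' @return Tibble with columns `time` (years) and `mass` (remaining
#'   fraction), suitable for the decay-curve fitters.
#' @export
decay_data <- function(traj) {
  tibble::tibble(time = traj$year, mass = traj$remaining_fraction)
}

decay_xy <- function(data, time, mass) {
  data <- tibble::as_tibble(data)
  for (col in c(time, mass)) {
    if (!col %in% names(data)) stop("column '", col, "' not found")
  }
  t <- data[[time]]
  m <- data[[mass]]
  if (any(!is.finite(t)) || any(!is.finite(m))) {
    stop("times and masses must be finite")
  }
  if (any(m <= 0)) stop("masses must be positive")
  list(t = t, m = m)
}

default_M0 <- function(t, m, M0) {
  if (!is.null(M0)) return(M0)
  if (any(t == 0)) m[t == 0][1] else max(m)
}

#' Fit a single-exponential decay curve
#'
#' Nonlinear least squares on the untransformed masses for
#' `M_t = M_0 * exp(-k t)`.  With `force_intercept = TRUE` the intercept is
#' fixed at `M0` (the mass at `t = 0` by default) and only `k` is free,
#' the convention for reporting a decomposition constant anchored at 100% of
#' the initial mass.  A log-linear regression alternative is available for
#' comparison.
#'
#' @param data Data frame of the decay series.
#' @param time,mass Column names for time (years) and (positive) mass.
#' @param force_intercept Fix the intercept at `M0`.
#' @param M0 Known initial mass; defaults to the mass at `t = 0`, else the
#'   maximum.
#' @param log_linear Fit by ordinary regression of `log(mass)` on time
#'   instead of nonlinear least squares.
#' @return An object of class `exp_fit` with elements `k` (y^-1), `M0`,
#'   `intercept_forced`, `r_squared` (squared Pearson correlation of
#'   observed and fitted values), `sse` and `non_decaying` (TRUE, with a
#'   warning, when the best fit has `k <= 0`).
#' @export
fit_single_exponential <- function(data, time = "time", mass = "mass",
                                   force_intercept = FALSE, M0 = NULL,
                                   log_linear = FALSE) {
  xy <- decay_xy(data, time, mass)
  t <- xy$t
  m <- xy$m
  if (length(t) < (if (force_intercept) 2 else 3)) {
    stop("need at least ", if (force_intercept) 2 else 3, " points")
  }
  M0_use <- default_M0(t, m, M0)
  ll <- stats::lm(log(m) ~ t)
  if (log_linear) {
    if (force_intercept) {
      k <- -sum(t * (log(m) - log(M0_use))) / sum(t^2)
    } else {
      k <- -stats::coef(ll)[[2]]
      M0_use <- exp(stats::coef(ll)[[1]])
    }
    fitted <- M0_use * exp(-k * t)
  } else {
    k0 <- max(-stats::coef(ll)[[2]], 1e-6)
    if (force_intercept) {
      fit <- minpack.lm::nlsLM(m ~ M0_use * exp(-k * t),
                               start = list(k = k0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
      k <- stats::coef(fit)[["k"]]
    } else {
      fit <- minpack.lm::nlsLM(m ~ A * exp(-k * t),
                               start = list(A = exp(stats::coef(ll)[[1]]),
                                            k = k0),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
      k <- stats::coef(fit)[["k"]]
      M0_use <- stats::coef(fit)[["A"]]
    }
    fitted <- M0_use * exp(-k * t)
  }
  non_decaying <- k <= 0
  if (non_decaying) warning("series is not decaying: fitted k <= 0")
  structure(
    list(k = k, M0 = M0_use, intercept_forced = force_intercept,
         r_squared = stats::cor(m, fitted)^2, sse = sum((m - fitted)^2),
         n = length(t), non_decaying = non_decaying,
         data = tibble::tibble(time = t, mass = m, fitted = fitted)),
    class = "exp_fit"
  )
}

#' Fit a power-exponential decay curve
#'
#' Nonlinear least squares for `M_t = M_0 * (t + 1)^k2 * exp(-k1 t)` with
#' `M0` fixed.  A positive `k2` bends the curve above the pure exponential
#' at early times (a colonization lag); the fit is started from a
#' deterministic 3 x 3 grid over `(k1, k2)` to avoid the local minima of
#' their trade-off, and the best converged start by SSE is kept.
#'
#' @inheritParams fit_single_exponential
#' @return An object of class `powexp_fit` with elements `k1`, `k2`, `M0`,
#'   `r_squared` and `sse`.
#' @export
fit_power_exponential <- function(data, time = "time", mass = "mass",
                                  M0 = NULL) {
  xy <- decay_xy(data, time, mass)
  t <- xy$t
  m <- xy$m
  if (length(t) < 4) stop("need at least 4 points")
  if (any(t < 0)) stop("times must be >= 0")
  M0_use <- default_M0(t, m, M0)
  starts <- expand.grid(k1 = c(0.05, 0.15, 0.45), k2 = c(-0.3, 0, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        m ~ M0_use * (t + 1)^k2 * exp(-k1 * t),
        start = list(k1 = starts$k1[i], k2 = starts$k2[i]),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(coef = stats::coef(fit), sse = sse)
    }
  }
  if (is.null(best)) {
    stop("power-exponential fit failed to converge from all ",
         nrow(starts), " starts (n = ", length(t), ")")
  }
  k1 <- best$coef[["k1"]]
  k2 <- best$coef[["k2"]]
  fitted <- M0_use * (t + 1)^k2 * exp(-k1 * t)
  structure(
    list(k1 = k1, k2 = k2, M0 = M0_use,
         r_squared = stats::cor(m, fitted)^2, sse = best$sse, n = length(t),
         data = tibble::tibble(time = t, mass = m, fitted = fitted)),
    class = "powexp_fit"
  )
}

#' Half-life of a single-exponential decay
#'
#' Closed form `T50 = -ln(0.5) / k`.
#'
#' @param k Decomposition constant, y^-1 (> 0).
#' @return One-row tibble with `t50_years` and `method`.
#' @export
half_life_exponential <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("k must be a single positive rate")
  }
  tibble::tibble(t50_years = -log(0.5) / k, method = "closed_form")
}

#' Half-life of a power-exponential decay
#'
#' The dual-constant curve `(t + 1)^k2 * exp(-k1 t)` has no closed-form
#' half-life; the crossing of 0.5 is found by doubling out a bracket and
#' bisecting `f(t) = (t + 1)^k2 * exp(-k1 t) - 0.5` to `|f| < 1e-9`.
#'
#' @param k1,k2 Decay constants of the power-exponential curve.
#' @return One-row tibble with `t50_years` and `method`.
#' @export
half_life_power_exponential <- function(k1, k2) {
  f <- function(t) (t + 1)^k2 * exp(-k1 * t) - 0.5
  hi <- 1
  while (f(hi) > 0 && hi <= 500) hi <- hi * 2
  if (f(hi) > 0) {
    stop("curve does not cross 50% remaining within (0, 500] years")
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-9 || (hi - lo) < 1e-13) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  tibble::tibble(t50_years = mid, method = "iterative")
}

#' Remaining mass fraction under a fitted decay model
#'
#' Evaluates the fitted functional form normalised to its intercept, so the
#' value at `t = 0` is 1.
#'
#' @param object An `exp_fit` or `powexp_fit`.
#' @param t Times in years (>= 0).
#' @return Fractions `M_t / M_0`.
#' @export
remaining_fraction <- function(object, t) {
  UseMethod("remaining_fraction")
}

#' @export
remaining_fraction.exp_fit <- function(object, t) {
  stopifnot(all(t >= 0))
  exp(-object$k * t)
}

#' @export
remaining_fraction.powexp_fit <- function(object, t) {
  stopifnot(all(t >= 0))
  (t + 1)^object$k2 * exp(-object$k1 * t)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "M0"), estimate = c(x$k, x$M0))
}

#' @export
tidy.powexp_fit <- function(x, ...) {
  tibble::tibble(term = c("k1", "k2", "M0"), estimate = c(x$k1, x$k2, x$M0))
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, M0 = x$M0, intercept_forced = x$intercept_forced,
    r.squared = x$r_squared, sse = x$sse, n = x$n,
    t50_years = if (x$k > 0) half_life_exponential(x$k)$t50_years
                else NA_real_
  )
}

#' @export
glance.powexp_fit <- function(x, ...) {
  tibble::tibble(
    k1 = x$k1, k2 = x$k2, M0 = x$M0, r.squared = x$r_squared, sse = x$sse,
    n = x$n,
    t50_years = half_life_power_exponential(x$k1, x$k2)$t50_years
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("Single-exponential decay fit",
      if (x$intercept_forced) "(intercept forced)" else "(free intercept)",
      "\n  k =", format(x$k, digits = 4), "y^-1;  M0 =",
      format(x$M0, digits = 4), ";  R^2 =", format(x$r_squared, digits = 3),
      "\n")
  invisible(x)
}

#' @export
print.powexp_fit <- function(x, ...) {
  cat("Power-exponential decay fit\n  k1 =", format(x$k1, digits = 4),
      "; k2 =", format(x$k2, digits = 4), ";  R^2 =",
      format(x$r_squared, digits = 3), "\n")
  invisible(x)
}

decay_fit_plot <- function(x, curve) {
  grid <- tibble::tibble(time = seq(min(x$data$time), max(x$data$time),
                                    length.out = 200))
  grid$mass <- curve(grid$time)
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$time, y = .data$mass)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Time (y)", y = "Mass") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exp_fit <- function(object, ...) {
  decay_fit_plot(object, function(t) object$M0 * exp(-object$k * t))
}

#' @export
autoplot.powexp_fit <- function(object, ...) {
  decay_fit_plot(object, function(t) {
    object$M0 * (t + 1)^object$k2 * exp(-object$k1 * t)
  })
}
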