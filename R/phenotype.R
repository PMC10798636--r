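#' Optical-density time series
#'
#' Light container for a background-subtracted OD600 growth curve.
#' Times must be strictly ascending and all OD values positive
#' (background subtraction is the caller's job; this constructor only
#' enforces positivity, as a semi-log fit needs `log(OD)`).
#'
#' @param times Sampling times in hours, strictly ascending, length >= 2.
#' @param od600 Optical densities (> 0), same length.
#' @param label Condition label (default "").
#' @return An `od_series` object (tibble with columns `time_h`, `od600`
#'   and a `label` attribute).
#' @export
od_series <- function(times, od600, label = "") {
  if (!is.numeric(times) || !is.numeric(od600) ||
      any(!is.finite(times)) || any(!is.finite(od600))) {
    gp_data_error("times and od600 must be finite numeric")
  }
  if (length(times) != length(od600)) gp_data_error("times and od600 lengths differ")
  if (length(times) < 2) gp_data_error("an OD series needs at least 2 points")
  if (any(diff(times) <= 0)) gp_data_error("times must be strictly ascending")
  if (any(od600 <= 0)) gp_data_error("all od600 values must be > 0")
  out <- tibble::tibble(time_h = as.numeric(times), od600 = as.numeric(od600))
  attr(out, "label") <- label
  class(out) <- c("od_series", class(out))
  out
}

#' Exponential growth rate by semi-log regression
#'
#' Ordinary least squares of `log(OD)` on time over a window of the
#' series: the slope is the growth rate `lambda`, the doubling time is
#' `log(2) / lambda`.  At least 4 points are required, mirroring
#' standard practice of sampling several times during steady-state
#' exponential growth.
#'
#' @param series An [od_series()] (or tibble with `time_h`, `od600`).
#' @param window Integer `c(start, end)` indices into the series;
#'   default is the whole series.
#' @return An `exponential_fit`: list with `lambda` (1/h),
#'   `doubling_time` (h, `Inf` if `lambda <= 0`), `window`, `r_squared`,
#'   `n_points`.
#' @examples
#' s <- gen_od_series(lambda = 0.7, od0 = 0.05, t_grid = seq(0, 3, 0.5))
#' fit_growth_rate(s)$lambda # 0.7
#' @export
fit_growth_rate <- function(series, window = NULL) {
  series <- as_od(series)
  n <- nrow(series)
  if (is.null(window)) window <- c(1L, n)
  if (length(window) != 2L || window[1] < 1 || window[2] > n || window[1] > window[2]) {
    gp_domain_error("`window` must be valid c(start, end) indices")
  }
  idx <- seq.int(window[1], window[2])
  if (length(idx) < 4) gp_insufficient_data_error("growth-rate fit needs >= 4 points")
  t <- series$time_h[idx]
  y <- log(series$od600[idx])
  fit <- stats::lm.fit(cbind(1, t), y)
  lambda <- unname(fit$coefficients[2])
  sst <- sum((y - mean(y))^2)
  sse <- sum(fit$residuals^2)
  r2 <- if (sst < .Machine$double.eps) 1 else max(0, 1 - sse / sst)
  structure(
    list(
      lambda = lambda,
      doubling_time = if (lambda > 0) log(2) / lambda else Inf,
      window = as.integer(window),
      r_squared = r2,
      n_points = length(idx),
      intercept = unname(fit$coefficients[1])
    ),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential_fit> lambda = %.4g /h, doubling time = %.4g h, r2 = %.4f (%d points)\n",
    x$lambda, x$doubling_time, x$r_squared, x$n_points
  ))
  invisible(x)
}

as_od <- function(series) {
  if (inherits(series, "od_series")) return(series)
  if (is.data.frame(series) && all(c("time_h", "od600") %in% names(series))) {
    return(od_series(series$time_h, series$od600))
  }
  gp_data_error("expected an od_series or a data frame with time_h and od600")
}

#' Automatic steady-state window selection
#'
#' Enumerates every contiguous window of at least `min_points` points,
#' keeps those whose semi-log fit has `r_squared >= r2_min`, and returns
#' the one with the largest fitted growth rate — ties broken by longer
#' window, then earlier start.  This automates the manual "pick points
#' during steady-state growth" step.
#'
#' @param series An [od_series()].
#' @param min_points Minimum window length (>= 4, default 4).
#' @param r2_min Minimum `r_squared` (in `(0, 1]`, default 0.99).
#' @return Integer `c(start, end)` window.
#' @export
auto_window <- function(series, min_points = 4L, r2_min = 0.99) {
  series <- as_od(series)
  if (min_points < 4) gp_domain_error("`min_points` must be >= 4")
  if (r2_min <= 0 || r2_min > 1) gp_domain_error("`r2_min` must be in (0, 1]")
  n <- nrow(series)
  best <- NULL
  for (start in seq_len(n)) {
    for (end in seq.int(start, n)) {
      if (end - start + 1L < min_points) next
      f <- fit_growth_rate(series, c(start, end))
      if (f$r_squared < r2_min) next
      cand <- list(window = c(start, end), lambda = f$lambda, len = end - start + 1L)
      if (is.null(best) ||
          cand$lambda > best$lambda + 1e-12 ||
          (abs(cand$lambda - best$lambda) <= 1e-12 && cand$len > best$len) ||
          (abs(cand$lambda - best$lambda) <= 1e-12 && cand$len == best$len &&
           cand$window[1] < best$window[1])) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    gp_selection_error(sprintf("no window of >= %d points reaches r2 >= %g", min_points, r2_min))
  }
  as.integer(best$window)
}

#' Detect the onset of a diauxic shift
#'
#' Estimates the instantaneous specific growth rate by centred finite
#' differences of `log(OD)` smoothed with a moving average
#' (`smooth` points, default 3), and reports the first time it falls
#' below `theta * lambda1` and stays below for `min_run` consecutive
#' points.  The persistence requirement (default 3) guards against
#' single-point noise excursions; with `min_run = 1` the criterion is
#' the bare first crossing.
#'
#' @param series An [od_series()].
#' @param lambda1 Pre-shift exponential growth rate (1/h, > 0).
#' @param theta Slowdown threshold as a fraction of `lambda1`, in
#'   `(0, 1)`; default 0.5.
#' @param smooth Moving-average width (odd, >= 1) for the rate estimate.
#' @param min_run Consecutive sub-threshold points required (>= 1).
#' @return `t_shift`, the time (h) of shift onset.
#' @export
detect_shift <- function(series, lambda1, theta = 0.5, smooth = 3L, min_run = 3L) {
  series <- as_od(series)
  check_scalar(lambda1, "lambda1")
  if (lambda1 <= 0) gp_domain_error("`lambda1` must be > 0")
  if (theta <= 0 || theta >= 1) gp_domain_error("`theta` must be in (0, 1)")
  if (smooth < 1 || smooth %% 2 == 0) gp_domain_error("`smooth` must be odd and >= 1")
  if (min_run < 1) gp_domain_error("`min_run` must be >= 1")
  t <- series$time_h
  y <- log(series$od600)
  n <- length(y)
  if (n < smooth + 4) gp_insufficient_data_error("series too short for shift detection")
  # centred differences at interior points
  rate <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  rate_t <- t[2:(n - 1)]
  if (smooth > 1) {
    rate <- stats::filter(rate, rep(1 / smooth, smooth), sides = 2)
    keep <- !is.na(rate)
    rate_t <- rate_t[keep]
    rate <- as.numeric(rate[keep])
  }
  below <- rate < theta * lambda1
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run == min_run) return(rate_t[i - min_run + 1L])
  }
  gp_noshift_error("growth rate never drops below the shift threshold")
}

#' Diauxic lag time by back-extrapolation
#'
#' Fits the post-shift exponential over `second_window` and
#' back-extrapolates it to the OD at shift onset: the lag is the time by
#' which regrowth is delayed relative to an instantaneous switch,
#' `lag = t* - t_shift` where `t*` is when the fitted second exponential
#' reaches `OD(t_shift)`.  For an exact second exponential the result is
#' independent of which reference point in the window is used; an
#' instantaneous switch gives lag 0.  Marginally negative estimates
#' (detection lands one grid point late on an instantaneous shift) are
#' truncated at 0.
#'
#' @param series An [od_series()].
#' @param t_shift Shift-onset time (h), typically from [detect_shift()].
#' @param second_window Integer `c(start, end)` indices of the post-shift
#'   exponential; must lie entirely after `t_shift` and contain >= 4
#'   points.
#' @param lambda1 Optional pre-shift rate to record in the result; if
#'   `NULL`, fitted on the points before `t_shift`.
#' @return A `diauxic_result`: list with `t_shift`, `lambda1`,
#'   `lambda2`, `lag` (h, >= 0).
#' @export
diauxic_lag <- function(series, t_shift, second_window, lambda1 = NULL) {
  series <- as_od(series)
  check_scalar(t_shift, "t_shift")
  if (length(second_window) != 2L) gp_domain_error("`second_window` must be c(start, end)")
  if (series$time_h[second_window[1]] <= t_shift) {
    gp_domain_error("`second_window` must lie entirely after t_shift")
  }
  fit2 <- fit_growth_rate(series, second_window)
  if (fit2$lambda <= 0) gp_noregrowth_error("no regrowth: post-shift growth rate is <= 0")

  if (is.null(lambda1)) {
    pre <- which(series$time_h <= t_shift)
    lambda1 <- if (length(pre) >= 4) fit_growth_rate(series, c(1L, max(pre)))$lambda else NA_real_
  }
  # log OD at shift onset, interpolated on the observed curve
  y_shift <- stats::approx(series$time_h, log(series$od600), xout = t_shift)$y
  t_star <- (y_shift - fit2$intercept) / fit2$lambda
  structure(
    list(
      t_shift = t_shift,
      lambda1 = lambda1,
      lambda2 = fit2$lambda,
      lag = max(0, t_star - t_shift)
    ),
    class = "diauxic_result"
  )
}

#' @export
print.diauxic_result <- function(x, ...) {
  cat(sprintf(
    "<diauxic_result> shift at %.3g h, lambda1 = %.3g, lambda2 = %.3g /h, lag = %.3g h\n",
    x$t_shift, x$lambda1, x$lambda2, x$lag
  ))
  invisible(x)
}

#' Colony-forming-unit plating observation(s)
#'
#' @param colonies Colony counts (integers >= 0).
#' @param dilution_factor Dilution factors (>= 1).
#' @param plated_volume_mL Plated volumes in mL (> 0).
#' @return Tibble of class `cfu_observation`, one row per plate.
#' @export
cfu_observation <- function(colonies, dilution_factor, plated_volume_mL) {
  n <- max(length(colonies), length(dilution_factor), length(plated_volume_mL))
  colonies <- rep_len(colonies, n)
  dilution_factor <- rep_len(dilution_factor, n)
  plated_volume_mL <- rep_len(plated_volume_mL, n)
  if (any(!is.finite(colonies)) || any(colonies < 0) || any(colonies != round(colonies))) {
    gp_domain_error("`colonies` must be non-negative integers")
  }
  if (any(!is.finite(dilution_factor)) || any(dilution_factor < 1)) {
    gp_domain_error("`dilution_factor` must be >= 1")
  }
  if (any(!is.finite(plated_volume_mL)) || any(plated_volume_mL <= 0)) {
    gp_domain_error("`plated_volume_mL` must be > 0")
  }
  out <- tibble::tibble(
    colonies = as.numeric(colonies),
    dilution_factor = as.numeric(dilution_factor),
    plated_volume_mL = as.numeric(plated_volume_mL)
  )
  class(out) <- c("cfu_observation", class(out))
  out
}

#' Viable-cell density from a plating observation
#'
#' `density = colonies * dilution_factor / plated_volume_mL`, CFU/mL.
#'
#' @param obs A [cfu_observation()] (or compatible data frame).
#' @return Numeric vector of densities, one per plate.
#' @export
cfu_density <- function(obs) {
  if (!is.data.frame(obs) ||
      !all(c("colonies", "dilution_factor", "plated_volume_mL") %in% names(obs))) {
    gp_data_error("expected a cfu_observation (colonies, dilution_factor, plated_volume_mL)")
  }
  obs$colonies * obs$dilution_factor / obs$plated_volume_mL
}

#' Starvation survival percentage from CFU platings
#'
#' Densities (CFU/mL) are averaged over replicate plates at each stage,
#' then `percent = 100 * final / initial`.  Averaging densities before
#' taking the ratio matches plating each biological replicate in
#' triplicate and reporting mean survival.  The result is invariant to
#' the dilution scheme, provided counts and dilutions are consistent.
#'
#' @param initial,final [cfu_observation()] tables (>= 1 row each).
#' @return Survival percentage (scalar, >= 0).  Per-plate densities are
#'   attached as attributes `initial_densities` / `final_densities`.
#' @examples
#' survival_percent(
#'   cfu_observation(200, 1e5, 0.1),
#'   cfu_observation(40, 2e4, 0.1)
#' ) # 4
#' @export
survival_percent <- function(initial, final) {
  d0 <- cfu_density(initial)
  d1 <- cfu_density(final)
  if (length(d0) < 1 || length(d1) < 1) gp_data_error("need >= 1 observation per stage")
  if (mean(d0) <= 0) gp_domain_error("initial density must be > 0")
  out <- 100 * mean(d1) / mean(d0)
  attr(out, "initial_densities") <- d0
  attr(out, "final_densities") <- d1
  out
}

#' Colony-area fold change between two timepoints
#'
#' Per-colony fold change `area_t1 / area_t0` for the same colonies
#' imaged at two times; returns the mean and sample standard deviation,
#' the range-extension summary for soft-agar motility assays.
#'
#' @param areas_t0,areas_t1 Paired positive areas (same colonies, same
#'   order).
#' @return List with `mean_fold`, `sd_fold` (`0` for a single colony),
#'   and the per-colony `folds`.
#' @export
colony_area_foldchange <- function(areas_t0, areas_t1) {
  if (length(areas_t0) != length(areas_t1)) {
    gp_data_error("area vectors must be paired (equal length)")
  }
  if (length(areas_t0) < 1) gp_data_error("need at least one colony")
  if (any(!is.finite(areas_t0)) || any(!is.finite(areas_t1)) ||
      any(areas_t0 <= 0) || any(areas_t1 <= 0)) {
    gp_data_error("all areas must be positive and finite")
  }
  folds <- areas_t1 / areas_t0
  list(
    mean_fold = mean(folds),
    sd_fold = if (length(folds) > 1) stats::sd(folds) else 0,
    folds = folds
  )
}

#' Fraction of colonies exhibiting swarming
#'
#' Given per-colony swarming flags, or areas plus a threshold, the
#' fraction of colonies scored as swarming.
#'
#' @param x Logical flags, or numeric colony areas.
#' @param area_threshold Threshold above which a colony counts as
#'   swarming (required when `x` is numeric).
#' @return Fraction in `[0, 1]`.
#' @export
swarming_fraction <- function(x, area_threshold = NULL) {
  if (length(x) == 0) gp_domain_error("need at least one colony")
  if (is.logical(x)) {
    if (any(is.na(x))) gp_data_error("flags must not be NA")
    return(mean(x))
  }
  if (!is.numeric(x) || any(!is.finite(x))) gp_data_error("areas must be finite numeric")
  if (is.null(area_threshold)) gp_domain_error("`area_threshold` is required for numeric areas")
  mean(x > area_threshold)
}
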