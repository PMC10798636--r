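#' End-to-end diauxic-shift analysis of one OD curve
#'
#' Convenience pipeline wiring together the single-step tools: a first
#' estimate of the pre-shift rate from the early part of the curve,
#' shift detection with [detect_shift()], a post-shift window taken from
#' the tail of the series, and the lag by back-extrapolation with
#' [diauxic_lag()].  The pre-shift rate is then refit on the points
#' before the detected shift.
#'
#' @param series An [od_series()].
#' @param theta,smooth,min_run Passed to [detect_shift()].
#' @param head_fraction Fraction of the series used for the initial
#'   pre-shift rate estimate (default 0.25).
#' @param tail_fraction Fraction of the series (from the end) used as
#'   the provisional post-shift window (default 0.2).
#' @param refine_margin_h Safety margin (h) past the provisional
#'   regrowth onset when the post-shift window is re-selected (default
#'   0.5).  After a first lag estimate from the tail window, the
#'   post-shift exponential is refit on every point later than
#'   `t_shift + lag_estimate + refine_margin_h`, which shortens the
#'   extrapolation distance and tightens the rate estimate; set to
#'   `NA` to skip the refinement.
#' @return A `diauxic_result` (see [diauxic_lag()]).
#' @export
analyze_diauxie <- function(series, theta = 0.5, smooth = 3L, min_run = 3L,
                            head_fraction = 0.25, tail_fraction = 0.2,
                            refine_margin_h = 0.5) {
  series <- as_od(series)
  n <- nrow(series)
  n_head <- max(4L, floor(head_fraction * n))
  lambda1 <- fit_growth_rate(series, c(1L, n_head))$lambda
  if (lambda1 <= 0) gp_noshift_error("no exponential growth in the head of the series")
  t_shift <- detect_shift(series, lambda1, theta = theta, smooth = smooth, min_run = min_run)

  n_tail <- max(4L, floor(tail_fraction * n))
  w2 <- c(n - n_tail + 1L, n)
  if (series$time_h[w2[1]] <= t_shift) {
    after <- which(series$time_h > t_shift)
    if (length(after) < 4) gp_insufficient_data_error("too few points after the shift")
    w2 <- c(after[1], n)
  }
  # refit lambda1 on the pre-shift points only
  pre <- which(series$time_h <= t_shift)
  if (length(pre) >= 4) lambda1 <- fit_growth_rate(series, c(1L, max(pre)))$lambda
  res <- diauxic_lag(series, t_shift, w2, lambda1 = lambda1)

  # re-select the post-shift window from the provisional lag: everything
  # safely past the estimated regrowth onset belongs to the second
  # exponential, and a longer window anchors the back-extrapolation
  if (!is.na(refine_margin_h)) {
    start_t <- t_shift + res$lag + refine_margin_h
    cand <- which(series$time_h >= start_t)
    if (length(cand) >= 4 && series$time_h[cand[1]] > t_shift) {
      res <- diauxic_lag(series, t_shift, c(cand[1], n), lambda1 = lambda1)
    }
  }
  res
}
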