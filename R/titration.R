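#' Growth rate under imposed catabolic-sector induction
#'
#' When cAMP (or another external signal) fixes the catabolic-sector
#' fraction `x` rather than letting regulation set it, the ribosomal
#' headroom is `y = phi_R_max - x - phi_0` and growth is limited by two
#' fluxes: nutrient influx `kappa_n * x` and translation
#' `kappa_t * y`.  Two combination rules are offered:
#'
#' * `"hard_min"` — `lambda = min(kappa_n * x, kappa_t * y)`: the
#'   smaller flux is limiting.  Its optimum reproduces the closed-form
#'   growth law exactly, so this is the default.
#' * `"harmonic"` — `lambda = (kappa_n * x * kappa_t * y) /
#'   (kappa_n * x + kappa_t * y)`: a smooth series-bottleneck
#'   alternative, bounded above by `"hard_min"` pointwise.
#'
#' Both vanish at `x = 0` (no catabolic proteome) and at
#' `x = phi_R_max - phi_0` (no ribosomal headroom): growth is maximal
#' only at an intermediate induction, which is why both under- and
#' over-induction slow growth.
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (> 0).
#' @param x Imposed induction fraction(s), in `[0, phi_R_max - phi_0]`.
#' @param mode `"hard_min"` (default) or `"harmonic"`.
#' @return Growth rate(s), 1/h, >= 0.
#' @export
titration_growth_rate <- function(ctx, kappa_n, x, mode = c("hard_min", "harmonic")) {
  stopifnot(inherits(ctx, "growth_context"))
  if (is.character(mode)) {
    if (!all(mode %in% c("hard_min", "harmonic"))) {
      gp_config_error(sprintf("unknown titration mode '%s'", mode[[1]]))
    }
    mode <- mode[[1]]
  }
  check_scalar(kappa_n, "kappa_n")
  if (kappa_n < 0) gp_domain_error("`kappa_n` must be >= 0")
  if (!is.numeric(x) || any(!is.finite(x))) gp_domain_error("`x` must be finite numeric")
  span <- ctx$phi_R_max - ctx$phi_0
  if (any(x < -1e-12) || any(x > span + 1e-12)) {
    gp_domain_error(sprintf("`x` must lie in [0, %g]", span))
  }
  x <- pmin(pmax(x, 0), span)
  y <- span - x
  influx <- kappa_n * x
  translation <- ctx$kappa_t * y
  if (mode == "hard_min") {
    pmin(influx, translation)
  } else {
    denom <- influx + translation
    ifelse(denom > 0, influx * translation / denom, 0)
  }
}

#' Optimal induction level and the growth rate it achieves
#'
#' For the `"hard_min"` rule the optimum sits where nutrient influx and
#' translation flux intersect:
#' `x_star = kappa_t * (phi_R_max - phi_0) / (kappa_n + kappa_t)`, at
#' which `lambda_star` equals the closed-form growth law — the
#' titration picture and the growth law are two views of the same
#' balance.  Better substrates (larger `kappa_n`) peak at lower
#' induction: `x_star` is strictly decreasing in `kappa_n`.
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (> 0).
#' @return List with `x_star` and `lambda_star`.
#' @examples
#' ctx <- growth_context(4, 0.1, 0.6)
#' optimal_induction(ctx, 1) # x_star = 0.4, lambda_star = 0.4
#' @export
optimal_induction <- function(ctx, kappa_n) {
  stopifnot(inherits(ctx, "growth_context"))
  check_scalar(kappa_n, "kappa_n")
  if (kappa_n <= 0) gp_domain_error("`kappa_n` must be > 0")
  x_star <- ctx$kappa_t * (ctx$phi_R_max - ctx$phi_0) / (kappa_n + ctx$kappa_t)
  list(x_star = x_star, lambda_star = kappa_n * x_star)
}

#' Model titration curve on a uniform induction grid
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (> 0).
#' @param n_points Number of grid points (>= 3) spanning
#'   `[0, phi_R_max - phi_0]`.
#' @param mode Flux-combination rule, see [titration_growth_rate()].
#' @return A `titration_curve`: tibble with columns `x`, `lambda` and a
#'   `mode` attribute.
#' @export
titration_curve <- function(ctx, kappa_n, n_points, mode = c("hard_min", "harmonic")) {
  stopifnot(inherits(ctx, "growth_context"))
  check_scalar(n_points, "n_points")
  if (n_points < 3) gp_domain_error("`n_points` must be >= 3")
  mode <- match.arg(mode)
  x <- seq(0, ctx$phi_R_max - ctx$phi_0, length.out = as.integer(n_points))
  new_titration_curve(x, titration_growth_rate(ctx, kappa_n, x, mode), mode)
}

new_titration_curve <- function(x, lambda, mode) {
  if (length(x) != length(lambda)) gp_data_error("x and lambda lengths differ")
  if (any(diff(x) <= 0)) gp_data_error("titration x values must be strictly ascending")
  if (any(lambda < 0)) gp_data_error("titration growth rates must be >= 0")
  out <- tibble::tibble(x = x, lambda = lambda)
  attr(out, "mode") <- mode
  class(out) <- c("titration_curve", class(out))
  out
}

#' Fit the nutrient quality of a substrate from a titration curve
#'
#' Least-squares estimate of `kappa_n` given a known [growth_context()],
#' the inverse problem for measured cAMP-titration data.  Only
#' `kappa_n` is fitted: one curve cannot identify all four model
#' parameters, and in the model's framing the substrate-specific unknown
#' is precisely the nutrient quality.  The search is a coarse grid over
#' `log10(kappa_n)` in `[-3, 3]` followed by golden-section refinement.
#'
#' @param curve A `titration_curve` (from [titration_curve()],
#'   [gen_titration_data()], or [read_titration()]); needs >= 5 points
#'   with the peak in the interior.
#' @param ctx The [growth_context()] the curve was measured under.
#' @param mode Flux-combination rule used for the model prediction;
#'   defaults to the curve's own `mode` attribute.
#' @return Estimated `kappa_n` (scalar).
#' @export
fit_titration <- function(curve, ctx, mode = NULL) {
  stopifnot(inherits(ctx, "growth_context"))
  if (!all(c("x", "lambda") %in% names(curve))) {
    gp_data_error("titration curve needs columns `x` and `lambda`")
  }
  if (nrow(curve) < 5) gp_fit_error("need >= 5 titration points to fit kappa_n")
  if (all(curve$lambda <= 0)) gp_fit_error("degenerate titration curve: all growth rates are zero")
  peak <- which.max(curve$lambda)
  if (peak == 1L || peak == nrow(curve)) {
    gp_fit_error("titration curve must span both sides of its peak")
  }
  if (is.null(mode)) mode <- attr(curve, "mode") %||% "hard_min"

  sse <- function(log10_kn) {
    pred <- titration_growth_rate(ctx, 10^log10_kn, curve$x, mode)
    sum((pred - curve$lambda)^2)
  }
  grid <- seq(-3, 3, by = 0.1)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  10^opt$minimum
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimum-induction summary across substrates
#'
#' For substrates sharing one [growth_context()] but differing in
#' nutrient quality, tabulates each substrate's optimal induction
#' `x_star` and peak growth rate `lambda_star`.  Because `x_star`
#' decreases and `lambda_star` increases with `kappa_n`, the two
#' columns are perfectly anticorrelated: poor substrates need high
#' induction (high cAMP) yet still grow slowest.
#'
#' @param ctx A [growth_context()].
#' @param kappa_n_list Named (or unnamed) vector/list of nutrient
#'   qualities, all > 0.
#' @return Tibble with columns `name`, `kappa_n`, `x_star`,
#'   `lambda_star`, sorted by `x_star` (ties keep name order).
#' @export
inverse_correlation_summary <- function(ctx, kappa_n_list) {
  stopifnot(inherits(ctx, "growth_context"))
  kn <- unlist(kappa_n_list)
  if (length(kn) == 0) gp_domain_error("`kappa_n_list` must be non-empty")
  if (any(!is.finite(kn)) || any(kn <= 0)) gp_domain_error("all kappa_n must be > 0")
  nms <- names(kn)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- paste0("substrate_", seq_along(kn))
  }
  rows <- lapply(seq_along(kn), function(i) {
    opt <- optimal_induction(ctx, kn[[i]])
    tibble::tibble(
      name = nms[[i]], kappa_n = kn[[i]],
      x_star = opt$x_star, lambda_star = opt$lambda_star
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$x_star, seq_len(nrow(out))), , drop = FALSE]
}
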