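#' Numerically solved flux balance
#'
#' Solves the steady-state balance
#' `kappa_t * (phi_R - phi_0) = kappa_n * (phi_R_max - phi_R)`
#' for `phi_R` by bisection on `[phi_0, phi_R_max]`, without using the
#' closed-form solution.  Exists as an independent numerical cross-check
#' of [growth_rate_closed_form()] and [steady_state_allocation()]; the
#' two routes agreeing to machine-level tolerance is one of the model
#' self-consistency checks the package ships.
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (>= 0), scalar.
#' @param tol Bisection tolerance on `phi_R` (default 1e-14; tight
#'   enough that the translated growth rate is accurate to well below
#'   1e-9 relative error across the whole parameter range).
#' @return List with `phi_R`, `phi_P` and `lambda` from the numeric root.
#' @export
flux_balance_allocation <- function(ctx, kappa_n, tol = 1e-14) {
  stopifnot(inherits(ctx, "growth_context"))
  check_scalar(kappa_n, "kappa_n")
  if (kappa_n < 0) gp_domain_error("`kappa_n` must be >= 0")

  # g(phi_R) = translation flux - nutrient influx; increasing in phi_R
  g <- function(phi_R) {
    ctx$kappa_t * (phi_R - ctx$phi_0) - kappa_n * (ctx$phi_R_max - phi_R)
  }
  lo <- ctx$phi_0
  hi <- ctx$phi_R_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break # interval at machine resolution
    if (g(mid) <= 0) lo <- mid else hi <- mid
  }
  phi_R <- (lo + hi) / 2
  list(
    phi_R = phi_R,
    phi_P = ctx$phi_R_max - phi_R,
    lambda = ctx$kappa_t * (phi_R - ctx$phi_0)
  )
}
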