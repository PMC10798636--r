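#' Global growth-law parameter set
#'
#' Bundles the substrate-independent parameters of the steady-state
#' growth-law model: the translational capacity `kappa_t` (growth rate per
#' unit ribosomal proteome fraction), the offset ribosomal fraction
#' `phi_0` (ribosomes present even at zero growth), and the maximum
#' combined catabolic + ribosomal fraction `phi_R_max`.  Two derived
#' quantities are computed, never user-set: the maximum growth rate
#' `lambda_max = kappa_t * (phi_R_max - phi_0)` and the growth-rate
#' invariant proteome fraction `phi_fixed = 1 - (phi_R_max - phi_0)`,
#' so that `lambda_max = (1 - phi_fixed) * kappa_t` holds by construction.
#'
#' The model itself fixes no numeric values for these parameters; the
#' defaults used in examples throughout the package are illustrative
#' round numbers, not measurements.
#'
#' @param kappa_t Translational capacity, 1/h per unit proteome fraction
#'   (> 0).
#' @param phi_0 Offset ribosomal fraction, dimensionless in `[0, 1)`.
#' @param phi_R_max Maximum combined P+R proteome fraction, dimensionless
#'   in `(phi_0, 1]`.
#' @return An object of class `growth_context` with elements `kappa_t`,
#'   `phi_0`, `phi_R_max`, `lambda_max`, `phi_fixed`.
#' @examples
#' ctx <- growth_context(kappa_t = 4, phi_0 = 0.1, phi_R_max = 0.6)
#' ctx$lambda_max # 2
#' @export
growth_context <- function(kappa_t, phi_0, phi_R_max) {
  check_scalar(kappa_t, "kappa_t")
  check_scalar(phi_0, "phi_0")
  check_scalar(phi_R_max, "phi_R_max")
  if (kappa_t <= 0) gp_domain_error("`kappa_t` must be > 0")
  if (phi_0 < 0 || phi_0 >= 1) gp_domain_error("`phi_0` must be in [0, 1)")
  if (phi_R_max <= phi_0 || phi_R_max > 1) {
    gp_domain_error("`phi_R_max` must satisfy phi_0 < phi_R_max <= 1")
  }
  structure(
    list(
      kappa_t = kappa_t,
      phi_0 = phi_0,
      phi_R_max = phi_R_max,
      lambda_max = kappa_t * (phi_R_max - phi_0),
      phi_fixed = 1 - (phi_R_max - phi_0)
    ),
    class = "growth_context"
  )
}

#' @export
print.growth_context <- function(x, ...) {
  cat("<growth_context>\n")
  cat(sprintf("  kappa_t    = %g /h per unit fraction\n", x$kappa_t))
  cat(sprintf("  phi_0      = %g\n", x$phi_0))
  cat(sprintf("  phi_R_max  = %g\n", x$phi_R_max))
  cat(sprintf("  lambda_max = %g /h (derived)\n", x$lambda_max))
  cat(sprintf("  phi_fixed  = %g (derived)\n", x$phi_fixed))
  invisible(x)
}

#' Per-substrate nutrient-quality parameters
#'
#' A substrate is characterised by a core nutrient quality
#' `kappa_n_star`, set by the catalytic properties of its dedicated
#' transporters and enzymes, and by the expression fraction `f` of those
#' proteins within the co-regulated catabolic (P) sector.  The effective
#' nutrient quality that enters the growth law is the product
#' `kappa_n = f * kappa_n_star`: quality is plastic because regulation
#' can move `f` without touching enzyme biochemistry.
#'
#' @param name Substrate label.
#' @param kappa_n_star Core nutrient quality, 1/h per unit proteome
#'   fraction (> 0).
#' @param f Expression fraction of substrate-specific proteins within the
#'   P-sector, in `(0, 1]`.
#' @return An object of class `substrate_params` with the effective
#'   `kappa_n` precomputed.
#' @examples
#' substrate_params("mannose", kappa_n_star = 10, f = 0.1)$kappa_n # 1
#' @export
substrate_params <- function(name, kappa_n_star, f) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    gp_domain_error("`name` must be a non-empty string")
  }
  structure(
    list(
      name = name,
      kappa_n_star = kappa_n_star,
      f = f,
      kappa_n = effective_nutrient_quality(kappa_n_star, f)
    ),
    class = "substrate_params"
  )
}

#' @export
print.substrate_params <- function(x, ...) {
  cat(sprintf(
    "<substrate_params> %s: kappa_n* = %g, f = %g, kappa_n = %g\n",
    x$name, x$kappa_n_star, x$f, x$kappa_n
  ))
  invisible(x)
}

#' Effective nutrient quality from core quality and expression fraction
#'
#' `kappa_n = f * kappa_n_star`.  The expression fraction `f` of the
#' substrate-specific core within the catabolic sector scales the core
#' enzymatic quality down to the quality the growth law actually sees.
#'
#' @param kappa_n_star Core nutrient quality (> 0).
#' @param f Expression fraction in `(0, 1]`.
#' @return Effective nutrient quality, same units as `kappa_n_star`.
#' @export
effective_nutrient_quality <- function(kappa_n_star, f) {
  check_scalar(kappa_n_star, "kappa_n_star")
  check_scalar(f, "f")
  if (kappa_n_star <= 0) gp_domain_error("`kappa_n_star` must be > 0")
  if (f <= 0 || f > 1) gp_domain_error("`f` must be in (0, 1]")
  f * kappa_n_star
}

#' Closed-form steady-state growth rate
#'
#' The Monod-like growth law obtained by balancing translation flux
#' `kappa_t * (phi_R - phi_0)` against nutrient influx
#' `kappa_n * phi_P` under the proteome constraint
#' `phi_R + phi_P = phi_R_max`:
#' \deqn{\lambda = \lambda_{max} \frac{\kappa_n}{\kappa_n + \kappa_t}.}
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (>= 0); may be a vector.
#' @return Growth rate(s) in 1/h, in `[0, lambda_max)`.
#' @examples
#' ctx <- growth_context(4, 0.1, 0.6)
#' growth_rate_closed_form(ctx, 4) # lambda_max / 2 = 1
#' @export
growth_rate_closed_form <- function(ctx, kappa_n) {
  stopifnot(inherits(ctx, "growth_context"))
  if (!is.numeric(kappa_n) || any(!is.finite(kappa_n))) {
    gp_domain_error("`kappa_n` must be finite numeric")
  }
  if (any(kappa_n < 0)) gp_domain_error("`kappa_n` must be >= 0")
  ctx$lambda_max * kappa_n / (kappa_n + ctx$kappa_t)
}

#' Steady-state proteome allocation on a substrate
#'
#' Solves the flux balance for the ribosomal fraction,
#' `phi_R = (kappa_t * phi_0 + kappa_n * phi_R_max) / (kappa_n + kappa_t)`,
#' and decomposes the catabolic sector into its substrate-specific core
#' `phi_C_star = f * phi_P` and the adaptability sector
#' `phi_AD = phi_P - phi_C_star`.
#'
#' @param ctx A [growth_context()].
#' @param substrate A [substrate_params()].
#' @return An object of class `sector_allocation`: list with `phi_R`,
#'   `phi_P`, `phi_C_star`, `phi_AD`, `lambda`.
#' @examples
#' ctx <- growth_context(4, 0.1, 0.6)
#' steady_state_allocation(ctx, substrate_params("mannose", 10, 0.1))
#' @export
steady_state_allocation <- function(ctx, substrate) {
  stopifnot(inherits(ctx, "growth_context"), inherits(substrate, "substrate_params"))
  kn <- substrate$kappa_n
  phi_R <- (ctx$kappa_t * ctx$phi_0 + kn * ctx$phi_R_max) / (kn + ctx$kappa_t)
  phi_P <- ctx$phi_R_max - phi_R
  phi_C_star <- substrate$f * phi_P
  structure(
    list(
      phi_R = phi_R,
      phi_P = phi_P,
      phi_C_star = phi_C_star,
      phi_AD = phi_P - phi_C_star,
      lambda = ctx$kappa_t * (phi_R - ctx$phi_0)
    ),
    class = "sector_allocation"
  )
}

#' @export
print.sector_allocation <- function(x, ...) {
  cat("<sector_allocation>\n")
  cat(sprintf("  phi_R = %.6g  phi_P = %.6g\n", x$phi_R, x$phi_P))
  cat(sprintf("  phi_C* = %.6g  phi_AD = %.6g\n", x$phi_C_star, x$phi_AD))
  cat(sprintf("  lambda = %.6g /h\n", x$lambda))
  invisible(x)
}

#' Infer nutrient quality from an observed growth rate
#'
#' Inverts the closed-form growth law:
#' `kappa_n = kappa_t * lambda / (lambda_max - lambda)`.  Observed rates
#' at or above `lambda_max` are infeasible under the model.
#'
#' @param ctx A [growth_context()].
#' @param lambda_obs Observed steady-state growth rate(s), 1/h, in
#'   `[0, lambda_max)`.
#' @return Effective nutrient quality (vectorised over `lambda_obs`).
#' @export
infer_kappa_n <- function(ctx, lambda_obs) {
  stopifnot(inherits(ctx, "growth_context"))
  if (!is.numeric(lambda_obs) || any(!is.finite(lambda_obs))) {
    gp_domain_error("`lambda_obs` must be finite numeric")
  }
  if (any(lambda_obs < 0)) gp_domain_error("`lambda_obs` must be >= 0")
  if (any(lambda_obs >= ctx$lambda_max)) {
    gp_infeasible_error(sprintf(
      "observed growth rate >= lambda_max (%g /h) is infeasible under the model",
      ctx$lambda_max
    ))
  }
  ctx$kappa_t * lambda_obs / (ctx$lambda_max - lambda_obs)
}

#' Predicted growth rate after re-engineering the expression fraction
#'
#' Promoter replacement changes the expression fraction of the
#' substrate-specific core within the catabolic sector from the
#' substrate's native `f` to `f_new`, leaving the core enzymatic quality
#' `kappa_n_star` untouched.  The predicted rate is the closed-form
#' growth law at `kappa_n = f_new * kappa_n_star`, so the growth rate on
#' a "poor" substrate can be dialed all the way up to that of a "good"
#' one by raising `f_new`.
#'
#' @param ctx A [growth_context()].
#' @param substrate A [substrate_params()].
#' @param f_new New expression fraction in `(0, 1]`.
#' @return Predicted growth rate, 1/h.
#' @export
predict_promoter_swap <- function(ctx, substrate, f_new) {
  stopifnot(inherits(ctx, "growth_context"), inherits(substrate, "substrate_params"))
  growth_rate_closed_form(
    ctx,
    effective_nutrient_quality(substrate$kappa_n_star, f_new)
  )
}

#' Adaptability sector from catabolic fraction and expression fraction
#'
#' The part of the catabolic sector not devoted to the current
#' substrate: `phi_AD = phi_P * (1 - f)`.  It holds alternative uptake
#' systems, stress and motility proteins — the preparatory reserve that
#' shrinks as `f` is pushed towards 1.
#'
#' @param phi_P Catabolic (P) sector fraction in `[0, 1]`.
#' @param f Expression fraction in `(0, 1]`.
#' @return Adaptability fraction `phi_AD >= 0`.
#' @export
adaptability_fraction <- function(phi_P, f) {
  check_scalar(phi_P, "phi_P")
  check_scalar(f, "f")
  if (phi_P < 0 || phi_P > 1) gp_domain_error("`phi_P` must be in [0, 1]")
  if (f <= 0 || f > 1) gp_domain_error("`f` must be in (0, 1]")
  phi_P * (1 - f)
}
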