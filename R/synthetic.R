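# Seeded synthetic-data generators.  Every generator is a pure function
# of its arguments including `seed`: the RNG state is set locally and
# restored, so the same call always yields byte-identical output and
# never disturbs the caller's RNG.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      gp_domain_error("`seed` must be a single integer")
    }
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# lognormal multiplicative noise with unit mean and given CV
lognorm_noise <- function(n, cv) {
  if (cv < 0) gp_domain_error("`noise_cv` must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an exponential OD600 growth curve
#'
#' `od(t) = od0 * exp(lambda * t) * eps_t` with i.i.d. unit-mean
#' lognormal noise of coefficient of variation `noise_cv`
#' (`noise_cv = 0` gives the exact exponential).
#'
#' @param lambda Growth rate, 1/h (>= 0).
#' @param od0 Initial OD (> 0).
#' @param t_grid Sampling times (h), strictly ascending.
#' @param noise_cv Multiplicative noise CV (>= 0, default 0).
#' @param seed Integer seed (default `NULL`: use current RNG state).
#' @param label Condition label.
#' @return An [od_series()].
#' @export
gen_od_series <- function(lambda, od0, t_grid, noise_cv = 0, seed = NULL, label = "simulated") {
  check_scalar(lambda, "lambda")
  check_scalar(od0, "od0")
  if (lambda < 0) gp_domain_error("`lambda` must be >= 0")
  if (od0 <= 0) gp_domain_error("`od0` must be > 0")
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    gp_domain_error("`t_grid` must be strictly ascending with >= 2 points")
  }
  with_seed(seed, {
    od <- od0 * exp(lambda * t_grid) * lognorm_noise(length(t_grid), noise_cv)
    od_series(t_grid, od, label = label)
  })
}

#' Simulate a diauxic OD600 curve with a known lag
#'
#' Exponential growth at `lambda1` from `od0` until the curve reaches
#' `od_shift` (first-substrate exhaustion), a flat plateau of duration
#' `lag`, then exponential regrowth at `lambda2`; multiplicative
#' lognormal noise on top.  The breakpoint time
#' `t_break = log(od_shift / od0) / lambda1` and all inputs are recorded
#' as attributes (`truth`) so recovery can be scored.
#'
#' @param lambda1,lambda2 Pre/post-shift growth rates (1/h; `lambda1 > 0`,
#'   `lambda2 >= 0` — zero gives a deliberate no-regrowth curve).
#' @param od0 Initial OD (> 0, default 0.02).
#' @param od_shift OD at first-substrate exhaustion (> `od0`).
#' @param lag Plateau duration, h (>= 0).
#' @param t_grid Sampling times (h), strictly ascending, must extend past
#'   `t_break`.
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @return An [od_series()] with attribute `truth` (list: `t_break`,
#'   `lag`, `lambda1`, `lambda2`, `od_shift`).
#' @export
gen_diauxic_series <- function(lambda1, od_shift, lag, lambda2, t_grid,
                               noise_cv = 0, seed = NULL, od0 = 0.02) {
  check_scalar(lambda1, "lambda1"); check_scalar(lambda2, "lambda2")
  check_scalar(od_shift, "od_shift"); check_scalar(lag, "lag"); check_scalar(od0, "od0")
  if (lambda1 <= 0) gp_domain_error("`lambda1` must be > 0")
  if (lambda2 < 0) gp_domain_error("`lambda2` must be >= 0")
  if (lag < 0) gp_domain_error("`lag` must be >= 0")
  if (od0 <= 0 || od_shift <= od0) gp_domain_error("need 0 < od0 < od_shift")
  t_break <- log(od_shift / od0) / lambda1
  if (t_break >= max(t_grid)) {
    gp_domain_error("`od_shift` is not reached within `t_grid`")
  }
  mean_od <- function(t) {
    ifelse(
      t <= t_break, od0 * exp(lambda1 * t),
      ifelse(
        t <= t_break + lag, od_shift,
        od_shift * exp(lambda2 * (t - t_break - lag))
      )
    )
  }
  with_seed(seed, {
    od <- mean_od(t_grid) * lognorm_noise(length(t_grid), noise_cv)
    out <- od_series(t_grid, od, label = "diauxic")
    attr(out, "truth") <- list(
      t_break = t_break, lag = lag,
      lambda1 = lambda1, lambda2 = lambda2, od_shift = od_shift
    )
    out
  })
}

#' Simulate joined proteomics input tables with known ground truth
#'
#' Emulates the statistical structure of the transporter-cost analysis:
#' per-substrate growth rates drawn uniformly from `lambda_range`, true
#' slow-condition copy numbers following the log-linear inverse relation
#' `copies_slow = exp(a - b * growth_rate) * eps` with lognormal noise
#' of CV `noise_cv`, fold changes uniform in `fc_range` (so that
#' `copies_per_cell = copies_slow / fold_change`), and protein lengths
#' uniform integers in `length_range`.  `n_decoys` extra genes are
#' appended, each present in exactly one table, to exercise the join.
#'
#' @param n_substrates Number of substrates (>= 3).
#' @param a Intercept of the log-copies relation (default 10, i.e.
#'   roughly 2e4 copies at zero growth rate).
#' @param b Slope (>= 0; default 6, about a 100-fold copy-number span
#'   across the default growth-rate range).  `b = 0` gives the null
#'   model with no copy-number/growth-rate relation.
#' @param noise_cv Lognormal noise CV on copy numbers (default 0.2).
#' @param fc_range Fold-change range (default `c(2, 8)`).
#' @param length_range Protein length range in amino acids (default
#'   `c(300, 700)`).
#' @param lambda_range Growth-rate range, 1/h (default `c(0.2, 1)`).
#' @param n_decoys Unjoinable decoy genes (default 0).
#' @param seed Integer seed.
#' @return List of tibbles `abundance`, `foldchange`, `substrates`,
#'   `truth` (latent copies_slow, cost, growth rate per substrate).
#' @export
gen_proteomics <- function(n_substrates, a = 10, b = 6, noise_cv = 0.2,
                           fc_range = c(2, 8), length_range = c(300L, 700L),
                           lambda_range = c(0.2, 1), n_decoys = 0L, seed = NULL) {
  check_scalar(n_substrates, "n_substrates")
  if (n_substrates < 3) gp_domain_error("`n_substrates` must be >= 3")
  if (b < 0) gp_domain_error("`b` must be >= 0")
  bad_range <- function(r) length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0
  if (bad_range(fc_range) || bad_range(length_range) || bad_range(lambda_range)) {
    gp_domain_error("ranges must be positive, finite, ordered pairs")
  }
  with_seed(seed, {
    n <- as.integer(n_substrates)
    gene <- sprintf("gene%03d", seq_len(n))
    substrate <- sprintf("substrate%03d", seq_len(n))
    growth_rate <- stats::runif(n, lambda_range[1], lambda_range[2])
    copies_slow <- exp(a - b * growth_rate) * lognorm_noise(n, noise_cv)
    fold_change <- stats::runif(n, fc_range[1], fc_range[2])
    copies_per_cell <- copies_slow / fold_change
    length_aa <- sample(seq.int(length_range[1], length_range[2]), n, replace = TRUE)

    abundance <- tibble::tibble(gene_id = gene, copies_per_cell = copies_per_cell,
                                length_aa = as.numeric(length_aa))
    foldchange <- tibble::tibble(gene_id = gene, fold_change = fold_change)
    substrates <- tibble::tibble(substrate = substrate, gene_id = gene,
                                 growth_rate = growth_rate)
    # decoys: round-robin, each present in exactly one table
    if (n_decoys > 0) {
      for (k in seq_len(n_decoys)) {
        id <- sprintf("decoy%03d", k)
        tab <- k %% 3L
        if (tab == 0L) {
          abundance <- rbind(abundance, tibble::tibble(
            gene_id = id, copies_per_cell = stats::runif(1, 100, 1000),
            length_aa = 400
          ))
        } else if (tab == 1L) {
          foldchange <- rbind(foldchange, tibble::tibble(
            gene_id = id, fold_change = stats::runif(1, fc_range[1], fc_range[2])
          ))
        } else {
          substrates <- rbind(substrates, tibble::tibble(
            substrate = sprintf("decoy_substrate%03d", k), gene_id = id,
            growth_rate = stats::runif(1, lambda_range[1], lambda_range[2])
          ))
        }
      }
    }
    truth <- tibble::tibble(
      substrate = substrate, gene_id = gene,
      copies_slow = copies_slow,
      cost_aa = copies_slow * length_aa,
      growth_rate = growth_rate
    )
    list(abundance = abundance, foldchange = foldchange,
         substrates = substrates, truth = truth)
  })
}

#' Simulate CFU plating counts
#'
#' Colony counts are Poisson with mean
#' `true_density * plated_volume_mL / dilution_factor`, independent
#' across replicate plates.
#'
#' @param true_density_per_mL True viable-cell density, CFU/mL (> 0).
#' @param dilution_factor Dilution before plating (>= 1).
#' @param plated_volume_mL Plated volume, mL (> 0).
#' @param n_replicates Number of replicate plates (>= 1).
#' @param seed Integer seed.
#' @return A [cfu_observation()] with `n_replicates` rows.
#' @export
gen_cfu <- function(true_density_per_mL, dilution_factor, plated_volume_mL,
                    n_replicates = 3L, seed = NULL) {
  check_scalar(true_density_per_mL, "true_density_per_mL")
  check_scalar(dilution_factor, "dilution_factor")
  check_scalar(plated_volume_mL, "plated_volume_mL")
  if (true_density_per_mL <= 0 || dilution_factor < 1 || plated_volume_mL <= 0 ||
      n_replicates < 1) {
    gp_domain_error("all gen_cfu parameters must be positive (dilution_factor >= 1)")
  }
  mu <- true_density_per_mL * plated_volume_mL / dilution_factor
  if (mu > 1e6) gp_domain_error("expected colony count > 1e6: not a countable plate")
  with_seed(seed, {
    cfu_observation(
      colonies = stats::rpois(as.integer(n_replicates), mu),
      dilution_factor = dilution_factor,
      plated_volume_mL = plated_volume_mL
    )
  })
}

#' Simulate a noisy cAMP-titration curve
#'
#' The model curve from [titration_curve()] plus additive Gaussian noise
#' truncated at zero; `noise_sd = 0` reproduces the model curve exactly.
#'
#' @param ctx A [growth_context()].
#' @param kappa_n Effective nutrient quality (> 0).
#' @param n_points Grid size (>= 3).
#' @param noise_sd Additive noise standard deviation, 1/h (>= 0).
#' @param seed Integer seed.
#' @param mode Flux-combination rule (default `"hard_min"`).
#' @return A `titration_curve` with attribute `truth = kappa_n`.
#' @export
gen_titration_data <- function(ctx, kappa_n, n_points, noise_sd = 0, seed = NULL,
                               mode = c("hard_min", "harmonic")) {
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) gp_domain_error("`noise_sd` must be >= 0")
  mode <- match.arg(mode)
  clean <- titration_curve(ctx, kappa_n, n_points, mode)
  with_seed(seed, {
    lambda <- pmax(0, clean$lambda + stats::rnorm(nrow(clean), 0, noise_sd))
    out <- new_titration_curve(clean$x, lambda, mode)
    attr(out, "truth") <- kappa_n
    out
  })
}
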