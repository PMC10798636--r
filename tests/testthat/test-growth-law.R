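test_that("growth context derives lambda_max and phi_fixed consistently", {
  ctx <- example_ctx()
  expect_equal(ctx$lambda_max, 2)
  expect_equal(ctx$phi_fixed, 0.5)
  expect_equal(ctx$lambda_max, (1 - ctx$phi_fixed) * ctx$kappa_t)

  expect_error(growth_context(-1, 0.1, 0.6), class = "gp_domain_error")
  expect_error(growth_context(4, 1.0, 0.6), class = "gp_domain_error")
  expect_error(growth_context(4, 0.3, 0.2), class = "gp_domain_error")
  expect_error(growth_context(4, 0.1, 1.2), class = "gp_domain_error")
})

test_that("effective nutrient quality scales core quality by expression fraction", {
  expect_equal(effective_nutrient_quality(10, 1), 10)
  expect_equal(effective_nutrient_quality(10, 0.1), 1)
  expect_error(effective_nutrient_quality(10, 0), class = "gp_domain_error")
  expect_error(effective_nutrient_quality(10, 1.5), class = "gp_domain_error")
  expect_error(effective_nutrient_quality(-1, 0.5), class = "gp_domain_error")
})

test_that("closed-form growth rate matches its limits and half-saturation point", {
  ctx <- example_ctx()
  expect_equal(growth_rate_closed_form(ctx, ctx$kappa_t), ctx$lambda_max / 2)
  expect_equal(growth_rate_closed_form(ctx, 0), 0)
  expect_equal(growth_rate_closed_form(ctx, 1), 0.4)
  expect_lt(growth_rate_closed_form(ctx, 1e9), ctx$lambda_max)
  expect_equal(growth_rate_closed_form(ctx, 1e12), ctx$lambda_max, tolerance = 1e-9)
  expect_error(growth_rate_closed_form(ctx, -1), class = "gp_domain_error")
})

test_that("steady-state allocation solves the flux balance and decomposes sectors", {
  ctx <- example_ctx()
  al <- steady_state_allocation(ctx, substrate_params("x", kappa_n_star = 1, f = 1))
  expect_equal(al$phi_R, 0.2)
  expect_equal(al$phi_P, 0.4)
  expect_equal(al$lambda, 0.4)
  expect_equal(al$phi_R + al$phi_P, ctx$phi_R_max, tolerance = 1e-12)

  # sector decomposition with a partial expression fraction
  al2 <- steady_state_allocation(ctx, substrate_params("mannose", 10, 0.1))
  expect_equal(al2$phi_C_star, 0.1 * al2$phi_P)
  expect_equal(al2$phi_AD, al2$phi_P - al2$phi_C_star)
  expect_gte(al2$phi_AD, 0)

  # zero-flux fixed point as kappa_n -> 0 (f bounded away from 0, so use
  # a tiny kappa_n_star)
  al0 <- steady_state_allocation(ctx, substrate_params("none", 1e-12, 1))
  expect_equal(al0$phi_R, ctx$phi_0, tolerance = 1e-9)
  expect_equal(al0$lambda, 0, tolerance = 1e-9)
})

test_that("closed form agrees with two independent numeric flux-balance solvers", {
  set.seed(11)
  for (i in 1:200) {
    ctx <- random_ctx()
    kn <- 10^runif(1, -2, 2)
    lam <- growth_rate_closed_form(ctx, kn)
    expect_equal(flux_balance_allocation(ctx, kn)$lambda, lam, tolerance = 1e-9)
    expect_equal(uniroot_allocation(ctx, kn)$lambda, lam, tolerance = 1e-8)
    al <- steady_state_allocation(ctx, substrate_params("s", kn, 1))
    expect_equal(al$lambda, lam, tolerance = 1e-9)
  }
})

test_that("growth rate is monotone in each parameter in the expected direction", {
  set.seed(7)
  for (i in 1:50) {
    ctx <- random_ctx()
    kn <- 10^runif(1, -1, 1)
    eps <- 1e-6
    lam <- growth_rate_closed_form(ctx, kn)
    expect_gt(growth_rate_closed_form(ctx, kn * (1 + eps)), lam)
    ctx_up <- growth_context(ctx$kappa_t, ctx$phi_0, min(1, ctx$phi_R_max + eps))
    expect_gt(growth_rate_closed_form(ctx_up, kn), lam)
    if (ctx$phi_0 > eps) {
      ctx_dn <- growth_context(ctx$kappa_t, ctx$phi_0 - eps, ctx$phi_R_max)
      expect_gt(growth_rate_closed_form(ctx_dn, kn), lam)
    }
  }
})

test_that("nutrient-quality inference inverts the growth law", {
  ctx <- example_ctx()
  expect_equal(infer_kappa_n(ctx, 1.0), 4)
  expect_equal(infer_kappa_n(ctx, 0), 0)
  expect_error(infer_kappa_n(ctx, ctx$lambda_max), class = "gp_infeasible_error")
  expect_error(infer_kappa_n(ctx, -0.1), class = "gp_domain_error")

  lambdas <- seq(0, 0.999 * ctx$lambda_max, length.out = 100)
  round_trip <- growth_rate_closed_form(ctx, infer_kappa_n(ctx, lambdas))
  expect_equal(round_trip, lambdas, tolerance = 1e-9)
})

test_that("promoter swap prediction is the growth law at the new expression fraction", {
  ctx <- example_ctx()
  sub <- substrate_params("mannose", kappa_n_star = 10, f = 0.1)
  expect_equal(predict_promoter_swap(ctx, sub, sub$f),
               steady_state_allocation(ctx, sub)$lambda)
  expect_equal(predict_promoter_swap(ctx, sub, 1), 2 * 10 / 14)
  # monotone non-decreasing in f, maximised at f = 1
  fs <- seq(0.05, 1, by = 0.05)
  lams <- vapply(fs, function(f) predict_promoter_swap(ctx, sub, f), numeric(1))
  expect_true(all(diff(lams) > 0))
  expect_equal(which.max(lams), length(fs))
})

test_that("adaptability fraction is the non-core share of the P sector", {
  expect_equal(adaptability_fraction(0.4, 0.125), 0.35)
  expect_equal(adaptability_fraction(0.4, 1), 0)
  expect_equal(adaptability_fraction(0, 0.5), 0)
  expect_error(adaptability_fraction(1.2, 0.5), class = "gp_domain_error")
  expect_error(adaptability_fraction(0.4, 0), class = "gp_domain_error")
})
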