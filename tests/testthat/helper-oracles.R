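# Shared fixtures and independent oracles.

# the illustrative parameter set used throughout the examples
example_ctx <- function() growth_context(kappa_t = 4, phi_0 = 0.1, phi_R_max = 0.6)

# independent flux-balance oracle: root of the balance equation via
# stats::uniroot, sharing no code with either package solver
uniroot_allocation <- function(ctx, kappa_n) {
  g <- function(phi_R) {
    ctx$kappa_t * (phi_R - ctx$phi_0) - kappa_n * (ctx$phi_R_max - phi_R)
  }
  phi_R <- stats::uniroot(g, c(ctx$phi_0, ctx$phi_R_max), tol = 1e-14)$root
  list(phi_R = phi_R, lambda = ctx$kappa_t * (phi_R - ctx$phi_0))
}

# random valid parameter draw for property tests
random_ctx <- function() {
  phi_0 <- runif(1, 0, 0.3)
  growth_context(
    kappa_t = runif(1, 0.5, 10),
    phi_0 = phi_0,
    phi_R_max = runif(1, phi_0 + 0.05, 1)
  )
}
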