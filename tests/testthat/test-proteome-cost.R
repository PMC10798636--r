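abc_tables <- function() {
  list(
    abundance = tibble::tibble(
      gene_id = c("a", "b", "c"),
      copies_per_cell = c(100, 200, 300),
      length_aa = c(500, 400, 300)
    ),
    foldchange = tibble::tibble(gene_id = c("b", "c", "d"), fold_change = c(2, 3, 4)),
    substrates = tibble::tibble(substrate = "mannose", gene_id = "c", growth_rate = 0.3)
  )
}

test_that("three-way join keeps only shared genes and reports drops", {
  tabs <- abc_tables()
  j <- join_datasets(tabs$abundance, tabs$foldchange, tabs$substrates)
  expect_equal(j$records$gene_id, "c")
  expect_equal(j$n_dropped, 3L) # a, b, d
  expect_setequal(j$dropped, c("a", "b", "d"))

  # identical gene sets: no drops
  genes <- c("x", "y", "z")
  j2 <- join_datasets(
    tibble::tibble(gene_id = genes, copies_per_cell = 1:3 * 100, length_aa = 400),
    tibble::tibble(gene_id = genes, fold_change = c(2, 2, 2)),
    tibble::tibble(substrate = genes, gene_id = genes, growth_rate = c(0.2, 0.5, 0.8))
  )
  expect_equal(j2$n_dropped, 0L)
  expect_equal(nrow(j2$records), 3L)

  expect_error(
    join_datasets(
      tabs$abundance,
      tibble::tibble(gene_id = "q", fold_change = 2),
      tabs$substrates
    ),
    class = "gp_analysis_error"
  )
  dup <- rbind(tabs$abundance, tabs$abundance[1, ])
  expect_error(join_datasets(dup, tabs$foldchange, tabs$substrates), class = "gp_data_error")
})

test_that("copy-number rescaling and amino-acid cost are simple products", {
  expect_equal(copies_at_reference(1000, 3), 3000)
  expect_equal(copies_at_reference(1000, 1), 1000)
  expect_error(copies_at_reference(0, 3), class = "gp_domain_error")
  expect_error(copies_at_reference(1000, -1), class = "gp_domain_error")

  expect_equal(protein_cost(3000, 500), 1.5e6)
  expect_equal(protein_cost(0, 500), 0)
  expect_error(protein_cost(3000, 0), class = "gp_domain_error")
})

test_that("rank correlation matches cor.test on exact and approximate branches", {
  r <- rank_correlation(c(5, 4, 3, 2, 1), c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(r$rho, -1)
  expect_equal(rank_correlation(1:5, 1:5 * 2)$rho, 1)

  # n = 5, no ties: exact permutation p equals cor.test's exact p
  x <- c(5, 1, 4, 2, 3); y <- c(0.2, 0.9, 0.3, 0.5, 0.8)
  r2 <- rank_correlation(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(r2$rho, unname(ct$estimate))
  expect_equal(r2$p_value, ct$p.value)
  expect_equal(r2$method, "exact permutation")

  # n = 12: t approximation branch vs cor.test
  set.seed(5)
  x12 <- rnorm(12); y12 <- x12 + rnorm(12)
  r3 <- rank_correlation(x12, y12)
  ct3 <- suppressWarnings(cor.test(x12, y12, method = "spearman", exact = FALSE))
  expect_equal(r3$rho, unname(ct3$estimate))
  expect_equal(r3$p_value, ct3$p.value, tolerance = 1e-10)

  # ties use average ranks
  rt <- rank_correlation(c(1, 1, 2, 3), c(10, 10, 20, 30))
  expect_equal(rt$rho, 1)

  expect_error(rank_correlation(1:2, 2:1), class = "gp_stats_error")
  expect_error(rank_correlation(c(1, 1, 1), 1:3), class = "gp_stats_error")
})

test_that("rank correlation is invariant under strictly monotone transforms", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    base <- rank_correlation(x, y)$rho
    expect_equal(rank_correlation(exp(x), y)$rho, base)
    expect_equal(rank_correlation(x, y^3)$rho, base)
    expect_equal(rank_correlation(100 * x + 7, atan(y))$rho, base)
  }
})

test_that("cost-growth analysis recovers a perfect inverse construction", {
  lam <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  genes <- paste0("g", 1:5)
  copies_slow <- exp(10 - 5 * lam) # strictly decreasing, no noise
  fc <- c(2, 3, 4, 5, 6)
  j <- join_datasets(
    tibble::tibble(gene_id = genes, copies_per_cell = copies_slow / fc, length_aa = 400),
    tibble::tibble(gene_id = genes, fold_change = fc),
    tibble::tibble(substrate = genes, gene_id = genes, growth_rate = lam)
  )
  res <- cost_growth_analysis(j)
  expect_equal(res$rho_copies, -1)
  expect_equal(res$rho_cost, -1)
  expect_equal(res$table$copies_slow, copies_slow)
  expect_equal(res$table$cost_aa, copies_slow * 400)
  expect_lte(nrow(res$table), 5)

  expect_error(cost_growth_analysis(j$records[1:2, ]), class = "gp_stats_error")
})

test_that("shuffling growth rates centres the rank correlation at zero", {
  dat <- gen_proteomics(20, noise_cv = 0.2, seed = 77)
  j <- join_datasets(dat$abundance, dat$foldchange, dat$substrates)
  set.seed(78)
  rhos <- replicate(100, {
    shuffled <- j$records
    shuffled$growth_rate <- sample(shuffled$growth_rate)
    cost_growth_analysis(shuffled)$rho_copies
  })
  expect_lt(abs(mean(rhos)), 0.15)
})
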