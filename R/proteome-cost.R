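#' Join abundance, fold-change and substrate tables on gene id
#'
#' Inner join across the three inputs of the protein-cost analysis:
#' absolute copy numbers measured in a fast reference condition, the
#' fold change from that condition to a common slow-growth reference,
#' and the substrate-to-transporter mapping with measured growth rates.
#' Genes absent from any table are dropped and counted.
#'
#' @param abundance Tibble/data.frame with columns `gene_id`,
#'   `copies_per_cell`, `length_aa`.
#' @param foldchange Columns `gene_id`, `fold_change`.
#' @param substrates Columns `substrate`, `gene_id`, `growth_rate`.
#' @return List with `records` (the joined tibble), `n_dropped` (genes in
#'   the union but not the intersection), and `dropped` (their ids).
#' @export
join_datasets <- function(abundance, foldchange, substrates) {
  need <- function(tab, cols, what) {
    if (nrow(tab) == 0) gp_data_error(sprintf("%s table is empty", what))
    missing <- setdiff(cols, names(tab))
    if (length(missing)) {
      gp_format_error(sprintf(
        "%s table is missing column(s): %s", what, paste(missing, collapse = ", ")
      ))
    }
    if (anyDuplicated(tab$gene_id)) {
      gp_data_error(sprintf("%s table has duplicated gene_id values", what))
    }
  }
  need(abundance, c("gene_id", "copies_per_cell", "length_aa"), "abundance")
  need(foldchange, c("gene_id", "fold_change"), "fold-change")
  need(substrates, c("substrate", "gene_id", "growth_rate"), "substrate")

  common <- Reduce(intersect, list(abundance$gene_id, foldchange$gene_id, substrates$gene_id))
  all_ids <- unique(c(abundance$gene_id, foldchange$gene_id, substrates$gene_id))
  dropped <- setdiff(all_ids, common)
  if (length(common) == 0) {
    gp_analysis_error(paste0(
      "no gene_id is shared by all three tables; ",
      "abundance: {", paste(abundance$gene_id, collapse = ","), "} ",
      "fold-change: {", paste(foldchange$gene_id, collapse = ","), "} ",
      "substrates: {", paste(substrates$gene_id, collapse = ","), "}"
    ))
  }
  sub <- substrates[substrates$gene_id %in% common, , drop = FALSE]
  ab <- abundance[match(sub$gene_id, abundance$gene_id), , drop = FALSE]
  fc <- foldchange[match(sub$gene_id, foldchange$gene_id), , drop = FALSE]
  records <- tibble::tibble(
    substrate = sub$substrate,
    gene_id = sub$gene_id,
    copies_per_cell = ab$copies_per_cell,
    length_aa = ab$length_aa,
    fold_change = fc$fold_change,
    growth_rate = sub$growth_rate
  )
  list(records = records, n_dropped = length(dropped), dropped = dropped)
}

#' Copy number rescaled to the slow-growth reference condition
#'
#' `copies_slow = copies_per_cell * fold_change`.  Copy numbers are
#' measured in one (glucose, fast) condition; multiplying by the
#' measured fold change to a common slow-growth reference (0.45 /h in
#' the source data sets) puts every transporter on the same footing.
#' Zero reference abundance is rejected: a fold change applied to zero
#' carries no information.
#'
#' @param copies_per_cell Copy number in the reference condition (> 0).
#' @param fold_change Slow/reference abundance ratio (> 0).
#' @return Copy number at the slow-growth condition (vectorised).
#' @export
copies_at_reference <- function(copies_per_cell, fold_change) {
  if (!is.numeric(copies_per_cell) || !is.numeric(fold_change) ||
      any(!is.finite(copies_per_cell)) || any(!is.finite(fold_change))) {
    gp_domain_error("inputs must be finite numeric")
  }
  if (any(copies_per_cell <= 0)) {
    gp_domain_error("`copies_per_cell` must be > 0 (zero reference abundance is uninformative)")
  }
  if (any(fold_change <= 0)) gp_domain_error("`fold_change` must be > 0")
  copies_per_cell * fold_change
}

#' Protein cost in amino acids per cell
#'
#' `cost_aa = copies_slow * length_aa`: copy number weighted by protein
#' size, the total amino-acid investment in that protein.
#'
#' @param copies_slow Copy number (>= 0).
#' @param length_aa Protein length in amino acids (>= 1).
#' @return Amino acids per cell (vectorised).
#' @export
protein_cost <- function(copies_slow, length_aa) {
  if (!is.numeric(copies_slow) || !is.numeric(length_aa) ||
      any(!is.finite(copies_slow)) || any(!is.finite(length_aa))) {
    gp_domain_error("inputs must be finite numeric")
  }
  if (any(copies_slow < 0)) gp_domain_error("`copies_slow` must be >= 0")
  if (any(length_aa < 1)) gp_domain_error("`length_aa` must be >= 1")
  copies_slow * length_aa
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' Spearman's rho computed as the Pearson correlation of average ranks
#' (midranks for ties).  For `n <= 8` the two-sided p-value is exact,
#' enumerating all `n!` orderings of one variable; for larger `n` it
#' uses the usual t approximation with `n - 2` degrees of freedom.
#'
#' @param values_x,values_y Paired numeric vectors, `n >= 3`, neither
#'   constant.
#' @return List with `rho`, `p_value`, `n` and `method` ("exact
#'   permutation" or "t approximation").
#' @export
rank_correlation <- function(values_x, values_y) {
  x <- as.numeric(values_x)
  y <- as.numeric(values_y)
  n <- length(x)
  if (n != length(y)) gp_data_error("x and y must have equal length")
  if (n < 3) gp_stats_error("need at least 3 pairs for a rank correlation")
  if (any(!is.finite(x)) || any(!is.finite(y))) gp_data_error("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    gp_stats_error("rank correlation is undefined for a constant vector")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)

  if (n <= 8) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}

# all n! permutations of 1:n as rows of a matrix (n <= 8 -> 40320 rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- row + seq_len(nrow(sub))
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' Protein-cost versus growth-rate integration analysis
#'
#' The full pipeline behind the transporter-cost anticorrelation: for
#' each substrate's transporter (or first catabolic enzyme), rescale its
#' copy number to the slow-growth reference, convert to amino-acid cost,
#' and rank-correlate both quantities against the growth rate the
#' wild type achieves on that substrate.  A negative rho says that
#' poorer substrates carry a larger protein investment in their uptake
#' machinery.  Pearson correlation of log cost vs growth rate is
#' reported as a secondary, parametric view.
#'
#' @param joined Joined records as produced by [join_datasets()] (either
#'   the list or its `records` tibble).
#' @return List with `table` (tibble: substrate, gene_id, copies_slow,
#'   cost_aa, growth_rate), `rho_copies`, `p_copies`, `rho_cost`,
#'   `p_cost`, and `pearson_log_cost`.
#' @export
cost_growth_analysis <- function(joined) {
  records <- if (is.list(joined) && !is.data.frame(joined) && !is.null(joined$records)) {
    joined$records
  } else {
    joined
  }
  need <- c("substrate", "gene_id", "copies_per_cell", "length_aa", "fold_change", "growth_rate")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    gp_format_error(sprintf("joined records missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(records) < 3) gp_stats_error("need >= 3 substrates after the join")

  copies_slow <- copies_at_reference(records$copies_per_cell, records$fold_change)
  cost_aa <- protein_cost(copies_slow, records$length_aa)
  tab <- tibble::tibble(
    substrate = records$substrate,
    gene_id = records$gene_id,
    copies_slow = copies_slow,
    cost_aa = cost_aa,
    growth_rate = records$growth_rate
  )
  rc <- rank_correlation(copies_slow, records$growth_rate)
  rk <- rank_correlation(cost_aa, records$growth_rate)
  list(
    table = tab,
    rho_copies = rc$rho, p_copies = rc$p_value,
    rho_cost = rk$rho, p_cost = rk$p_value,
    pearson_log_cost = stats::cor(log(cost_aa), records$growth_rate)
  )
}
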