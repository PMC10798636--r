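# Tabular IO.  Canonical dialect: tab-separated, UTF-8, "." decimal,
# one header line.  Readers validate schema and invariants at load and
# report the offending file, line and column; writers round-trip
# losslessly through their readers.

read_table_checked <- function(path, columns, sep = "\t") {
  if (!file.exists(path)) gp_format_error(sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = ""),
    error = function(e) gp_format_error(sprintf("%s: cannot parse (%s)", path, conditionMessage(e)))
  )
  missing <- setdiff(names(columns), names(tab))
  if (length(missing)) {
    gp_format_error(sprintf(
      "%s: missing column(s) %s", path, paste(missing, collapse = ", ")
    ))
  }
  for (col in names(columns)) {
    if (columns[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(v) & !is.na(tab[[col]]))
      if (length(bad)) {
        gp_format_error(sprintf(
          "%s: line %d, column '%s': not a number ('%s')",
          path, bad[1] + 1L, col, tab[[col]][bad[1]]
        ))
      }
      if (anyNA(v)) {
        gp_format_error(sprintf(
          "%s: line %d, column '%s': missing value",
          path, which(is.na(v))[1] + 1L, col
        ))
      }
      tab[[col]] <- v
    } else {
      tab[[col]] <- as.character(tab[[col]])
    }
  }
  tibble::as_tibble(tab[names(columns)])
}

check_positive_col <- function(tab, col, path, strict = TRUE) {
  bad <- if (strict) which(tab[[col]] <= 0) else which(tab[[col]] < 0)
  if (length(bad)) {
    gp_format_error(sprintf(
      "%s: line %d, column '%s': value %g violates %s",
      path, bad[1] + 1L, col, tab[[col]][bad[1]],
      if (strict) "> 0" else ">= 0"
    ))
  }
}

sep_for <- function(csv) if (csv) "," else "\t"

write_tsv_plain <- function(tab, path, sep = "\t") {
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an OD600 time series
#'
#' Columns: `time_h`, `od600` (optional `label`).
#'
#' @param path File path.
#' @param csv Read/write comma-separated instead of tab-separated.
#' @return `read_od_series()`: an [od_series()]; writers return the path
#'   invisibly.
#' @export
read_od_series <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(time_h = "numeric", od600 = "numeric"), sep_for(csv))
  check_positive_col(tab, "od600", path)
  if (any(diff(tab$time_h) <= 0)) {
    gp_format_error(sprintf("%s: column 'time_h' must be strictly ascending", path))
  }
  od_series(tab$time_h, tab$od600)
}

#' @param series An [od_series()].
#' @rdname read_od_series
#' @export
write_od_series <- function(series, path, csv = FALSE) {
  series <- as_od(series)
  write_tsv_plain(series[, c("time_h", "od600")], path, sep_for(csv))
}

#' Read / write CFU plating tables
#'
#' Columns: `stage` (`initial` or `final`), `colonies`,
#' `dilution_factor`, `plated_volume_mL`, `replicate`.
#'
#' @param path File path.
#' @param csv Comma-separated instead of tab-separated.
#' @return A list with `initial` and `final` [cfu_observation()] tables.
#' @export
read_cfu <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(
    stage = "character", colonies = "numeric", dilution_factor = "numeric",
    plated_volume_mL = "numeric", replicate = "character"
  ), sep_for(csv))
  bad <- which(!tab$stage %in% c("initial", "final"))
  if (length(bad)) {
    gp_format_error(sprintf(
      "%s: line %d, column 'stage': must be 'initial' or 'final'", path, bad[1] + 1L
    ))
  }
  check_positive_col(tab, "colonies", path, strict = FALSE)
  check_positive_col(tab, "plated_volume_mL", path)
  split_obs <- function(stage) {
    sub <- tab[tab$stage == stage, , drop = FALSE]
    if (nrow(sub) == 0) gp_format_error(sprintf("%s: no '%s' rows", path, stage))
    cfu_observation(sub$colonies, sub$dilution_factor, sub$plated_volume_mL)
  }
  list(initial = split_obs("initial"), final = split_obs("final"))
}

#' @param initial,final [cfu_observation()] tables.
#' @rdname read_cfu
#' @export
write_cfu <- function(initial, final, path, csv = FALSE) {
  stamp <- function(obs, stage) {
    tibble::tibble(
      stage = stage, colonies = obs$colonies,
      dilution_factor = obs$dilution_factor,
      plated_volume_mL = obs$plated_volume_mL,
      replicate = as.character(seq_len(nrow(obs)))
    )
  }
  write_tsv_plain(rbind(stamp(initial, "initial"), stamp(final, "final")), path, sep_for(csv))
}

#' Read / write colony-area tables
#'
#' Columns: `colony_id`, `day`, `area`.
#'
#' @param path File path.
#' @param csv Comma-separated instead of tab-separated.
#' @return Tibble with the three columns.
#' @export
read_areas <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(
    colony_id = "character", day = "numeric", area = "numeric"
  ), sep_for(csv))
  check_positive_col(tab, "area", path)
  tab
}

#' @param areas Tibble with `colony_id`, `day`, `area`.
#' @rdname read_areas
#' @export
write_areas <- function(areas, path, csv = FALSE) {
  write_tsv_plain(areas[, c("colony_id", "day", "area")], path, sep_for(csv))
}

#' Read / write proteomics input tables
#'
#' Abundance columns: `gene_id`, `copies_per_cell`, `length_aa`;
#' fold-change columns: `gene_id`, `fold_change`; substrate columns:
#' `substrate`, `gene_id`, `growth_rate`.
#'
#' @param path File path.
#' @param csv Comma-separated instead of tab-separated.
#' @return A tibble with the validated columns.
#' @export
read_abundance <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(
    gene_id = "character", copies_per_cell = "numeric", length_aa = "numeric"
  ), sep_for(csv))
  check_positive_col(tab, "copies_per_cell", path)
  bad <- which(tab$length_aa < 1)
  if (length(bad)) {
    gp_format_error(sprintf("%s: line %d, column 'length_aa': must be >= 1", path, bad[1] + 1L))
  }
  tab
}

#' @rdname read_abundance
#' @export
read_foldchange <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(gene_id = "character", fold_change = "numeric"), sep_for(csv))
  check_positive_col(tab, "fold_change", path)
  tab
}

#' @rdname read_abundance
#' @export
read_substrates <- function(path, csv = FALSE) {
  tab <- read_table_checked(path, c(
    substrate = "character", gene_id = "character", growth_rate = "numeric"
  ), sep_for(csv))
  check_positive_col(tab, "growth_rate", path)
  tab
}

#' @param tab A tibble of the matching schema.
#' @rdname read_abundance
#' @export
write_abundance <- function(tab, path, csv = FALSE) {
  write_tsv_plain(tab[, c("gene_id", "copies_per_cell", "length_aa")], path, sep_for(csv))
}

#' @rdname read_abundance
#' @export
write_foldchange <- function(tab, path, csv = FALSE) {
  write_tsv_plain(tab[, c("gene_id", "fold_change")], path, sep_for(csv))
}

#' @rdname read_abundance
#' @export
write_substrates <- function(tab, path, csv = FALSE) {
  write_tsv_plain(tab[, c("substrate", "gene_id", "growth_rate")], path, sep_for(csv))
}

#' Read / write titration curves
#'
#' Two columns, `x` (induction fraction, strictly ascending) and
#' `lambda` (growth rate, 1/h).
#'
#' @param path File path.
#' @param csv Comma-separated instead of tab-separated.
#' @param mode Flux-combination rule recorded on the returned curve.
#' @return A `titration_curve`.
#' @export
read_titration <- function(path, csv = FALSE, mode = "hard_min") {
  tab <- read_table_checked(path, c(x = "numeric", lambda = "numeric"), sep_for(csv))
  new_titration_curve(tab$x, tab$lambda, mode)
}

#' @param curve A `titration_curve`.
#' @rdname read_titration
#' @export
write_titration <- function(curve, path, csv = FALSE) {
  write_tsv_plain(curve[, c("x", "lambda")], path, sep_for(csv))
}

#' Read model configuration from a YAML file
#'
#' Expected keys: `kappa_t`, `phi_0`, `phi_R_max`, and optionally a
#' `substrates` list of `{name, kappa_n_star, f}` entries.
#'
#' @param path YAML file path.
#' @return List with `ctx` (a [growth_context()]) and `substrates` (list
#'   of [substrate_params()], possibly empty).
#' @export
read_growth_config <- function(path) {
  if (!file.exists(path)) gp_config_error(sprintf("config file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) gp_config_error(sprintf("%s: %s", path, conditionMessage(e))))
  for (key in c("kappa_t", "phi_0", "phi_R_max")) {
    if (is.null(cfg[[key]])) gp_config_error(sprintf("%s: missing key '%s'", path, key))
  }
  ctx <- growth_context(cfg$kappa_t, cfg$phi_0, cfg$phi_R_max)
  substrates <- lapply(cfg$substrates %||% list(), function(s) {
    for (key in c("name", "kappa_n_star", "f")) {
      if (is.null(s[[key]])) gp_config_error(sprintf("%s: substrate entry missing '%s'", path, key))
    }
    substrate_params(s$name, s$kappa_n_star, s$f)
  })
  list(ctx = ctx, substrates = substrates)
}

#' Molarity of a media component
#'
#' `molarity_mM = 1000 * mass_g / (formula_weight_da * volume_L)`, the
#' arithmetic behind a salt-stock recipe table.
#'
#' @param mass_g Mass weighed in, grams (> 0).
#' @param formula_weight_da Formula weight, Daltons (> 0).
#' @param volume_L Final volume, litres (> 0).
#' @return Molarity in mM.
#' @examples
#' round_half_away(media_molarity(4, 174.26, 1), 1) # 23.0 (K2SO4)
#' @export
media_molarity <- function(mass_g, formula_weight_da, volume_L) {
  if (!is.numeric(mass_g) || !is.numeric(formula_weight_da) || !is.numeric(volume_L) ||
      any(!is.finite(c(mass_g, formula_weight_da, volume_L))) ||
      any(c(mass_g, formula_weight_da, volume_L) <= 0)) {
    gp_domain_error("mass, formula weight and volume must all be > 0")
  }
  1000 * mass_g / (formula_weight_da * volume_L)
}

#' Round half away from zero
#'
#' Companion to [media_molarity()] for comparison against printed recipe
#' tables, which use conventional half-away-from-zero rounding rather
#' than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
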