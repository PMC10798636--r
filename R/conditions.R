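# Classed conditions used across the package.  Every user-facing error
# carries "gp_error" plus a specific subclass so callers (and tests) can
# distinguish a bad parameter from a malformed file or an infeasible fit.

gp_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "gp_error"))
}

gp_domain_error <- function(message) gp_abort(message, "gp_domain_error")
gp_infeasible_error <- function(message) {
  gp_abort(message, c("gp_infeasible_error", "gp_domain_error"))
}
gp_config_error <- function(message) gp_abort(message, "gp_config_error")
gp_format_error <- function(message) gp_abort(message, "gp_format_error")
gp_data_error <- function(message) gp_abort(message, "gp_data_error")
gp_stats_error <- function(message) gp_abort(message, "gp_stats_error")
gp_analysis_error <- function(message) gp_abort(message, "gp_analysis_error")
gp_fit_error <- function(message) gp_abort(message, "gp_fit_error")
gp_selection_error <- function(message) gp_abort(message, "gp_selection_error")
gp_noshift_error <- function(message) gp_abort(message, "gp_noshift_error")
gp_noregrowth_error <- function(message) gp_abort(message, "gp_noregrowth_error")
gp_insufficient_data_error <- function(message) {
  gp_abort(message, "gp_insufficient_data_error")
}
gp_usage_error <- function(message) gp_abort(message, "gp_usage_error")

# scalar numeric check used by most constructors
check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gp_domain_error(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
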