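`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("depcohort_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), field = field)
  ))
}

domain_error <- function(msg) {
  stop(structure(
    class = c("depcohort_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

infeasible_error <- function(msg, state = NULL) {
  stop(structure(
    class = c("depcohort_infeasible_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), state = state)
  ))
}

#' Read a value from a scenario configuration by dotted path
#'
#' Paths address nested fields, e.g. `"costs.daily_wage"`,
#' `"run.horizon"` or `"costs.service_unit_costs.gp"`.
#'
#' @param cfg a `scenario_config` (or plain nested list)
#' @param path dotted field path
#' @return the value at `path`
#' @export
get_param <- function(cfg, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- cfg
  for (key in parts) {
    ok <- (is.list(x) || (!is.null(names(x)))) && key %in% names(x)
    if (!ok) config_error(sprintf("parameter path '%s' does not resolve (at '%s')", path, key), field = path)
    x <- x[[key]]
  }
  x
}

#' Set a value in a scenario configuration by dotted path
#'
#' @inheritParams get_param
#' @param value replacement value
#' @return the modified configuration
#' @export
set_param <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  rec <- function(x, parts) {
    key <- parts[[1]]
    ok <- (is.list(x) || (!is.null(names(x)))) && key %in% names(x)
    if (!ok) config_error(sprintf("parameter path '%s' does not resolve (at '%s')", path, key), field = path)
    if (length(parts) == 1L) {
      x[[key]] <- value
    } else {
      x[[key]] <- rec(x[[key]], parts[-1])
    }
    x
  }
  out <- rec(cfg, parts)
  class(out) <- class(cfg)
  out
}

# point estimate of the turnover cost multiplier used in deterministic runs:
# midpoint of the configured uniform range
turnover_midpoint <- function(cfg) {
  r <- cfg$costs$turnover_cost_multiplier_range
  mean(as.numeric(r))
}
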