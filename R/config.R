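# Analysis configuration: YAML schema holding every model input, strict
# validation, and assembly of the package objects from a parsed config.

CONFIG_TOP_KEYS <- c("model", "arms", "costs", "ae_costs", "ae_incidence",
                     "utilities", "accrual", "schedule", "wtp_thresholds",
                     "psa", "currency")

#' Path of the shipped base-case configuration
#'
#' The published Table-1 inputs (two-arm Weibull survival parameters, unit
#' costs with bounds, grade >= 3 AE incidences, utilities, 5% discounting,
#' 28-day cycles, 10-year horizon, WTP threshold $34,138.28).
#' @export
base_config_path <- function() {
  system.file("extdata", "paloma3_inputs.yaml", package = "palboCEA",
              mustWork = TRUE)
}

check_bounded <- function(x, field, unit_interval = FALSE) {
  for (key in c("base", "lower", "upper", "distribution"))
    if (is.null(x[[key]]))
      stop(sprintf("config: field '%s' is missing '%s'", field, key))
  if (!(x$lower <= x$base && x$base <= x$upper))
    stop(sprintf("config: field '%s' violates lower <= base <= upper", field))
  if (unit_interval && (x$lower < 0 || x$upper > 1))
    stop(sprintf("config: field '%s' must lie in [0, 1]", field))
  if (!x$distribution %in% c("gamma", "beta", "normal", "fixed"))
    stop(sprintf("config: field '%s' has unknown distribution '%s'",
                 field, x$distribution))
  invisible(x)
}

#' Load and validate an analysis configuration
#'
#' Reads the YAML dialect documented in the shipped example
#' ([base_config_path()]): structural settings, per-arm parametric survival
#' models, unit costs / AE incidences / utilities each carrying `base`,
#' `lower`, `upper` and `distribution`, accrual rules, dosing schedule, WTP
#' thresholds and PSA settings. Unknown top-level keys and missing or
#' invalid fields are rejected with an error naming the field.
#'
#' @param path YAML file path.
#' @return validated config, class `cea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a raw config list to validate.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), CONFIG_TOP_KEYS)
  if (length(unknown))
    stop("config: unknown top-level key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(CONFIG_TOP_KEYS, names(config))
  if (length(missing))
    stop("config: missing section(s): ", paste(missing, collapse = ", "))

  m <- config$model
  for (key in c("cycle_length_days", "horizon_years", "discount_rate",
                "background_mortality"))
    if (is.null(m[[key]])) stop("config: model is missing '", key, "'")
  check_bounded(m$discount_rate, "model.discount_rate")
  if (is.null(m$background_mortality$value) ||
      is.null(m$background_mortality$timescale))
    stop("config: model.background_mortality needs 'value' and 'timescale'")

  if (length(config$arms) < 2) stop("config: need at least two arms")
  for (arm in names(config$arms)) {
    a <- config$arms[[arm]]
    for (key in c("label", "includes_palbociclib", "pfs", "os"))
      if (is.null(a[[key]]))
        stop(sprintf("config: arm '%s' is missing '%s'", arm, key))
    for (ep in c("pfs", "os"))
      if (is.null(a[[ep]]$family))
        stop(sprintf("config: arm '%s' %s needs a 'family'", arm, ep))
  }

  for (field in names(config$costs))
    check_bounded(config$costs[[field]], paste0("costs.", field))
  for (field in names(config$ae_costs))
    check_bounded(config$ae_costs[[field]], paste0("ae_costs.", field))
  for (arm in names(config$ae_incidence))
    for (field in names(config$ae_incidence[[arm]]))
      check_bounded(config$ae_incidence[[arm]][[field]],
                    paste0("ae_incidence.", arm, ".", field),
                    unit_interval = TRUE)
  if (!setequal(names(config$ae_incidence), names(config$arms)))
    stop("config: ae_incidence arms must match the configured arms")
  for (field in c("pfs", "pd")) {
    if (is.null(config$utilities[[field]]))
      stop("config: utilities is missing '", field, "'")
    check_bounded(config$utilities[[field]], paste0("utilities.", field),
                  unit_interval = TRUE)
  }

  if (!is.numeric(unlist(config$wtp_thresholds)) || !length(config$wtp_thresholds))
    stop("config: wtp_thresholds must be a non-empty numeric list")
  if (is.null(config$psa$n_draws) || is.null(config$psa$seed))
    stop("config: psa needs 'n_draws' and 'seed'")

  # delegate the remaining checks to the constructors
  config_settings(structure(config, class = "cea_config"))
  config_inputs(structure(config, class = "cea_config"))
  config_schedule(structure(config, class = "cea_config"))
  for (arm in names(config$arms))
    for (ep in c("pfs", "os"))
      config_surv(structure(config, class = "cea_config"), arm, ep)
  structure(config, class = "cea_config")
}

#' Write a configuration back to YAML
#'
#' @param config a `cea_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname load_config
#' @export
config_settings <- function(config) {
  m <- config$model
  model_settings(cycle_length_days = m$cycle_length_days,
                 horizon_years = m$horizon_years,
                 discount_rate_annual = m$discount_rate$base,
                 background_mortality = m$background_mortality$value,
                 background_mortality_timescale = m$background_mortality$timescale)
}

#' @rdname load_config
#' @export
config_inputs <- function(config) {
  base_of <- function(section) vapply(section, `[[`, numeric(1), "base")
  econ_inputs(costs = base_of(config$costs),
              ae_costs = base_of(config$ae_costs),
              ae_incidence = lapply(config$ae_incidence, base_of),
              utilities = c(pfs = config$utilities$pfs$base,
                            pd = config$utilities$pd$base),
              accrual = config$accrual)
}

#' @rdname load_config
#' @export
config_schedule <- function(config) {
  do.call(dosing_schedule, config$schedule)
}

#' @rdname load_config
#' @param arm arm name.
#' @param endpoint `"pfs"` or `"os"`.
#' @export
config_surv <- function(config, arm, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  spec <- config$arms[[arm]][[endpoint]]
  if (is.null(spec)) stop("config_surv: unknown arm '", arm, "'")
  do.call(surv_model, spec)
}

#' Apply parameter overrides to a configuration
#'
#' Overrides are a named numeric vector keyed by dotted paths as produced
#' by [parameter_table()], e.g. `costs.palbociclib_per_cycle`,
#' `ae_incidence.palbociclib.neutropenia`, `utilities.pfs`,
#' `model.discount_rate`. Each override replaces the field's `base` value.
#'
#' @param config a `cea_config`.
#' @param overrides named numeric vector (may be empty or NULL).
#' @return the modified config.
#' @export
apply_overrides <- function(config, overrides) {
  if (is.null(overrides) || !length(overrides)) return(config)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- config
    for (p in parts) {
      node <- node[[p]]
      if (is.null(node)) stop("apply_overrides: unknown parameter '", nm, "'")
    }
    config[[c(parts, "base")]] <- unname(overrides[[nm]])
  }
  config
}

#' Evaluate the two-arm model for a configuration
#'
#' Runs the full pipeline (transitions, trace, half-cycle correction,
#' costs, QALYs, comparison) for the first two configured arms; the first
#' arm is treated as the intervention.
#'
#' @param config a `cea_config`.
#' @param overrides optional parameter overrides, see [apply_overrides()].
#' @return list with one `arm_outcome` per arm and `comparison`.
#' @export
evaluate_config <- function(config, overrides = NULL) {
  config <- apply_overrides(config, overrides)
  settings <- config_settings(config)
  inputs <- config_inputs(config)
  schedule <- config_schedule(config)
  arms <- lapply(names(config$arms), function(arm)
    run_arm(config_surv(config, arm, "pfs"), config_surv(config, arm, "os"),
            inputs, schedule, settings, arm,
            include_palbociclib = isTRUE(config$arms[[arm]]$includes_palbociclib)))
  names(arms) <- names(config$arms)
  out <- arms
  out$comparison <- compare(arms[[1]], arms[[2]])
  out
}

#' Base-case analysis
#'
#' Evaluates the configuration and judges cost-effectiveness of the
#' intervention arm against every configured WTP threshold.
#'
#' @param config a `cea_config`.
#' @return a `base_case_result`: arm outcomes, `comparison`, and a
#'   `verdicts` data frame (wtp, cost_effective).
#' @export
run_base_case <- function(config) {
  res <- evaluate_config(config)
  cmp <- res$comparison
  wtp <- unlist(config$wtp_thresholds)
  ce <- if (cmp$dominance == "dominant") rep(TRUE, length(wtp))
        else if (cmp$dominance %in% c("dominated", "undefined")) rep(FALSE, length(wtp))
        else cmp$delta_qaly * wtp - cmp$delta_cost > 0
  structure(c(res, list(verdicts = data.frame(wtp = wtp, cost_effective = ce))),
            class = "base_case_result")
}

#' @export
print.base_case_result <- function(x, ...) {
  arms <- Filter(function(e) inherits(e, "arm_outcome"), x)
  cat("Base case results\n")
  for (a in arms)
    cat(sprintf("  %-12s cost $%10.2f   %6.4f QALYs\n",
                a$arm, a$total_cost, a$total_qaly))
  cmp <- x$comparison
  cat(sprintf("  incremental  cost $%10.2f   %6.4f QALYs   %s\n",
              cmp$delta_cost, cmp$delta_qaly,
              if (is.na(cmp$icer)) cmp$dominance
              else sprintf("ICER $%.2f/QALY", cmp$icer)))
  for (i in seq_len(nrow(x$verdicts)))
    cat(sprintf("  at WTP $%.2f/QALY: %s\n", x$verdicts$wtp[i],
                if (x$verdicts$cost_effective[i]) "cost-effective"
                else "not cost-effective"))
  invisible(x)
}
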