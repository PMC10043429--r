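# Synthetic fixtures: censored event-time samples from known parametric
# models (to exercise fitting), Kaplan-Meier coordinate tables emulating
# digitized survival curves, and perturbed economic-input sets.

#' Simulate censored individual patient data
#'
#' Event times are drawn by inverse-transform sampling from the model's
#' survival function (`T = S^{-1}(U)`, `U ~ Uniform(0,1)`); right-censoring
#' is then applied. `"administrative"` censors everything at `t_max`
#' (default 79.6 cycles, about the 73.3-month data maturity of the trial
#' follow-up the fits emulate); `"uniform"` draws censoring times from
#' `Uniform(0, t_max)`; `"none"` observes every event.
#'
#' @param model a [surv_model()] (the true data-generating model).
#' @param n number of patients.
#' @param censoring `"none"`, `"uniform"` or `"administrative"`.
#' @param t_max censoring bound (required unless `censoring = "none"`).
#' @param seed RNG seed; all randomness flows from it.
#' @return data frame with columns `time` (> 0) and `event` (1 observed,
#'   0 censored).
#' @export
simulate_ipd <- function(model, n, censoring = c("none", "uniform",
                                                 "administrative"),
                         t_max = 79.6, seed = 1L) {
  censoring <- match.arg(censoring)
  stopifnot(inherits(model, "surv_model"), n >= 1)
  if (censoring != "none" && (is.null(t_max) || t_max <= 0))
    stop("simulate_ipd: t_max must be > 0 when censoring is active")
  set.seed(seed)
  t_event <- survival_inverse(model, stats::runif(n))
  c_time <- switch(censoring,
    none = rep(Inf, n),
    uniform = stats::runif(n, 0, t_max),
    administrative = rep(t_max, n))
  data.frame(time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time))
}

#' Kaplan-Meier coordinates on a time grid
#'
#' Product-limit survival estimates (via [survival::survfit()]) evaluated
#' at the requested grid points, emulating a digitized published curve.
#'
#' @param samples data frame with `time` and `event` columns.
#' @param grid non-negative time points.
#' @return data frame with `time` and `survival` (step function,
#'   non-increasing, 1 at time 0).
#' @export
km_coordinates <- function(samples, grid) {
  if (!nrow(samples)) stop("km_coordinates: empty sample")
  if (any(grid < 0)) stop("km_coordinates: grid times must be >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = samples)
  s <- summary(fit, times = grid, extend = TRUE)
  data.frame(time = s$time, survival = s$surv)
}

#' Redraw the economic inputs from their PSA distributions
#'
#' One probabilistic draw applied to the configuration: every uncertain
#' parameter is replaced by a sample from its moment-matched distribution
#' (costs Gamma, incidences and utilities Beta, discount rate Normal),
#' respecting the model constraints (resampling invalid combinations).
#' The result is a valid configuration; since a draw from an unbounded
#' distribution may fall outside the configured 95% interval, the field's
#' `lower`/`upper` bounds are widened where needed to keep containing the
#' new base value.
#'
#' @param config a `cea_config`.
#' @param seed RNG seed.
#' @return the perturbed `cea_config`.
#' @export
perturb_econ_inputs <- function(config, seed = 1L) {
  psa <- run_psa(config, n_draws = 1, seed = seed)
  v <- attr(psa, "samples")[1, ]
  config <- apply_overrides(config, v)
  for (nm in names(v)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- config[[parts]]
    node$lower <- min(node$lower, node$base)
    node$upper <- max(node$upper, node$base)
    config[[parts]] <- node
  }
  validate_config(config)
}
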