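# Parametric survival models for extrapolating PFS and OS beyond trial
# follow-up, per-cycle transition probabilities, and maximum-likelihood
# fitting to right-censored event times with AIC/BIC model selection.

SURV_FAMILIES <- c("weibull", "exponential", "lognormal", "loglogistic",
                   "gompertz", "generalized_gamma")

#' Parametric survival model
#'
#' Constructs a parametric survival model for one of six families. The
#' Weibull uses the rate parameterization `S(t) = exp(-scale * t^shape)`
#' (scale = lambda, shape = gamma), the form in which the published model
#' inputs are reported; gamma = 1 reduces to the exponential with rate
#' lambda. The remaining families use the standard parameterizations of
#' [stats] and [flexsurv]:
#'
#' * `exponential`: `rate` (> 0)
#' * `lognormal`: `meanlog`, `sdlog` (> 0)
#' * `loglogistic`: `shape`, `scale` (both > 0), as [flexsurv::pllogis()]
#' * `gompertz`: `shape` (real), `rate` (> 0), as [flexsurv::pgompertz()];
#'   for `shape < 0` the survival function plateaus above zero (improper),
#'   which is permitted for fitted objects but flagged by [is_proper()]
#' * `generalized_gamma`: `mu`, `sigma` (> 0), `Q`, the stable
#'   Prentice parameterization of [flexsurv::pgengamma()]; it nests the
#'   Weibull (`sigma = Q`) and lognormal (`Q = 0`)
#'
#' @param family one of `"weibull"`, `"exponential"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"generalized_gamma"`.
#' @param ... named numeric parameters for the family (see Details).
#' @return an object of class `surv_model`.
#' @examples
#' m <- surv_model("weibull", shape = 0.95501, scale = 0.06497)
#' survival_at(m, 0:12)
#' @export
surv_model <- function(family = SURV_FAMILIES, ...) {
  family <- match.arg(family)
  pars <- list(...)
  if (length(pars) && (is.null(names(pars)) || any(!nzchar(names(pars)))))
    stop("all parameters of a surv_model must be named")
  pars <- vapply(pars, as.numeric, numeric(1))
  need <- switch(family,
    weibull            = c("shape", "scale"),
    exponential        = "rate",
    lognormal          = c("meanlog", "sdlog"),
    loglogistic        = c("shape", "scale"),
    gompertz           = c("shape", "rate"),
    generalized_gamma  = c("mu", "sigma", "Q"))
  missing <- setdiff(need, names(pars))
  if (length(missing))
    stop(sprintf("surv_model('%s') requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")))
  pars <- pars[need]
  if (any(!is.finite(pars)))
    stop("surv_model parameters must be finite")
  pos <- switch(family,
    weibull           = c("shape", "scale"),
    exponential       = "rate",
    lognormal         = "sdlog",
    loglogistic       = c("shape", "scale"),
    gompertz          = "rate",
    generalized_gamma = "sigma")
  bad <- pos[pars[pos] <= 0]
  if (length(bad))
    stop(sprintf("surv_model('%s'): parameter(s) %s must be > 0",
                 family, paste(bad, collapse = ", ")))
  structure(list(family = family, params = pars), class = "surv_model")
}

#' @export
print.surv_model <- function(x, ...) {
  cat(sprintf("<surv_model: %s | %s>\n", x$family,
              paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}

#' Does the survival function reach zero?
#'
#' `TRUE` unless the model is a Gompertz with negative shape, whose survival
#' function plateaus at `exp(rate/shape)` as t grows.
#' @param model a [surv_model()].
#' @export
is_proper <- function(model) {
  !(model$family == "gompertz" && model$params[["shape"]] < 0)
}

#' Survival probability S(t)
#'
#' Evaluates the survival function of a parametric model at time `t`
#' (model time units; cycles in this package). For the Weibull this is
#' `exp(-lambda * t^gamma)`.
#'
#' @param model a [surv_model()].
#' @param t non-negative time(s), vectorized.
#' @return survival probabilities in `[0, 1]`, with `S(0) = 1`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("survival_at: t must be finite and >= 0")
  p <- model$params
  switch(model$family,
    weibull     = exp(-p[["scale"]] * t^p[["shape"]]),
    exponential = exp(-p[["rate"]] * t),
    lognormal   = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                            Q = p[["Q"]], lower.tail = FALSE))
}

#' Inverse survival function
#'
#' Returns the time `t` at which `S(t) = s`. Used by the synthetic-data
#' generator (inverse-transform sampling) and for median checks.
#'
#' @param model a [surv_model()].
#' @param s survival probabilities in `(0, 1]`, vectorized.
#' @export
survival_inverse <- function(model, s) {
  stopifnot(inherits(model, "surv_model"))
  if (any(s <= 0) || any(s > 1))
    stop("survival_inverse: s must lie in (0, 1]")
  p <- model$params
  switch(model$family,
    weibull     = (-log(s) / p[["scale"]])^(1 / p[["shape"]]),
    exponential = -log(s) / p[["rate"]],
    lognormal   = stats::qlnorm(s, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(s, shape = p[["shape"]], scale = p[["scale"]],
                                    lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(s, shape = p[["shape"]], rate = p[["rate"]],
                                      lower.tail = FALSE),
    generalized_gamma = flexsurv::qgengamma(s, mu = p[["mu"]], sigma = p[["sigma"]],
                                            Q = p[["Q"]], lower.tail = FALSE))
}

#' Per-cycle transition probability
#'
#' Conditional probability of leaving the state during cycle `t` given
#' occupancy at the start of the cycle, `P(t) = 1 - S(t)/S(t-1)`. For the
#' Weibull this is evaluated in the closed form
#' `P(t) = 1 - exp(lambda*(t-1)^gamma - lambda*t^gamma)`; the general
#' survival-ratio form is used for the other families. The two agree to
#' numerical precision, which the test suite asserts.
#'
#' @param model a [surv_model()].
#' @param t cycle index (>= 1), vectorized.
#' @return probabilities in `[0, 1]`.
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(!is.finite(t)) || any(t < 1))
    stop("transition_prob: cycle index t must be >= 1")
  if (model$family == "weibull") {
    p <- model$params
    pr <- 1 - exp(p[["scale"]] * (t - 1)^p[["shape"]] - p[["scale"]] * t^p[["shape"]])
  } else {
    s0 <- survival_at(model, t - 1)
    # once S underflows to 0 the state is numerically extinct: exit for sure
    pr <- ifelse(s0 > 0, 1 - survival_at(model, t) / s0, 1)
  }
  pmin(pmax(pr, 0), 1)
}

n_free_params <- function(family) {
  switch(family,
    exponential = 1L,
    generalized_gamma = 3L,
    2L)
}

flexsurv_dist <- function(family) {
  switch(family,
    weibull = "weibull", exponential = "exp", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz",
    generalized_gamma = "gengamma")
}

# Convert a converged flexsurvreg fit back to this package's parameterization.
model_from_flexsurv <- function(fit, family) {
  # drop = FALSE keeps the parameter names for one-parameter families
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  switch(family,
    weibull = surv_model("weibull", shape = est[["shape"]],
                         scale = est[["scale"]]^(-est[["shape"]])),
    exponential = surv_model("exponential", rate = est[["rate"]]),
    lognormal = surv_model("lognormal", meanlog = est[["meanlog"]],
                           sdlog = est[["sdlog"]]),
    loglogistic = surv_model("loglogistic", shape = est[["shape"]],
                             scale = est[["scale"]]),
    gompertz = surv_model("gompertz", shape = est[["shape"]], rate = est[["rate"]]),
    generalized_gamma = surv_model("generalized_gamma", mu = est[["mu"]],
                                   sigma = est[["sigma"]], Q = est[["Q"]]))
}

#' Fit a parametric survival model to right-censored data
#'
#' Maximum-likelihood fit of one distribution family to censored event
#' times, via [flexsurv::flexsurvreg()]. Input follows the CSV dialect used
#' throughout the package: a data frame with columns `time` (> 0, cycles)
#' and `event` (1 = event observed, 0 = right-censored).
#'
#' @param data data frame with numeric `time` and 0/1 `event` columns.
#' @param family distribution family, see [surv_model()].
#' @return a `fit_report`: list with elements `model` ([surv_model()]),
#'   `family`, `log_likelihood`, `aic`, `bic`, `k` (free parameters),
#'   `n` (records), `converged`.
#' @export
fit_parametric <- function(data, family = SURV_FAMILIES) {
  family <- match.arg(family)
  if (!is.data.frame(data) || !all(c("time", "event") %in% names(data)))
    stop("fit_parametric: data must have columns 'time' and 'event'")
  if (any(data$time <= 0)) stop("fit_parametric: all times must be > 0")
  if (!all(data$event %in% c(0, 1)))
    stop("fit_parametric: event must be 0 (censored) or 1 (observed)")
  if (nrow(data) < 10)
    stop("fit_parametric: need at least 10 records")
  if (sum(data$event) < 1)
    stop("fit_parametric: non-identifiable, all records are censored")
  n <- nrow(data)
  k <- n_free_params(family)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = data,
                          dist = flexsurv_dist(family)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(model = NULL, family = family,
                          log_likelihood = NA_real_, aic = NA_real_,
                          bic = NA_real_, k = k, n = n, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "fit_report"))
  }
  ll <- fit$loglik
  structure(list(model = model_from_flexsurv(fit, family), family = family,
                 log_likelihood = ll, aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll, k = k, n = n, converged = TRUE),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<fit_report: %s | failed: %s>\n", x$family, x$message))
  } else {
    cat(sprintf("<fit_report: %s | loglik=%.3f AIC=%.3f BIC=%.3f n=%d>\n",
                x$family, x$log_likelihood, x$aic, x$bic, x$n))
  }
  invisible(x)
}

#' Select the preferred fit among candidate families
#'
#' Minimizes AIC; ties are broken by BIC, then by fewest free parameters.
#' Non-converged reports are never selected.
#'
#' @param reports list of `fit_report` objects on the same data.
#' @return the winning `fit_report`.
#' @export
select_model <- function(reports) {
  if (inherits(reports, "fit_report")) reports <- list(reports)
  if (!length(reports)) stop("select_model: empty collection of fit reports")
  ok <- vapply(reports, function(r) isTRUE(r$converged), logical(1))
  if (!any(ok)) stop("select_model: no converged fits to choose from")
  reports <- reports[ok]
  aic <- vapply(reports, `[[`, numeric(1), "aic")
  bic <- vapply(reports, `[[`, numeric(1), "bic")
  k   <- vapply(reports, `[[`, numeric(1), "k")
  reports[[order(aic, bic, k)[1]]]
}

#' Flat key-value serialization of a fit report
#'
#' @param report a `fit_report`.
#' @param path file to write; omit to return the lines invisibly.
#' @export
write_fit_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "fit_report"))
  pars <- if (is.null(report$model)) character(0) else
    sprintf("param_%s: %.10g", names(report$model$params), report$model$params)
  lines <- c(sprintf("family: %s", report$family), pars,
             sprintf("loglik: %.10g", report$log_likelihood),
             sprintf("aic: %.10g", report$aic),
             sprintf("bic: %.10g", report$bic),
             sprintf("n: %d", report$n),
             sprintf("converged: %s", report$converged))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
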