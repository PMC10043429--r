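# Discounted cost and QALY accumulation over a corrected cohort trace,
# and incremental comparison (ICER) between arms.

#' Economic inputs
#'
#' Base-case unit costs (USD), adverse-event (grade >= 3) management costs
#' and per-arm incidences, state utilities, and the accrual rules mapping
#' cost categories to health states.
#'
#' Accrual rules (package defaults, see the methods vignette for the
#' calibration rationale):
#' * drug acquisition and administration costs accrue while on treatment,
#'   i.e. with PFS membership (treatment continues to progression);
#' * `supportive_care` accrues in the state named by
#'   `accrual$supportive_care` (default `"pfs"`);
#' * `followup` accrues in the state named by `accrual$followup`
#'   (default `"alive"` = PFS + PD);
#' * terminal care is paid once per death, at the cycle of death;
#' * AE management cost is the incidence-weighted sum over the arm's AEs;
#'   with `accrual$ae_mode = "per_cycle"` (default) it accrues per cycle of
#'   PFS membership, with `"once"` it is charged once at model entry.
#'
#' @param costs named list/vector with elements `palbociclib_per_cycle`,
#'   `fulvestrant_per_250mg`, `followup_per_cycle`,
#'   `administration_per_cycle`, `supportive_care_per_cycle`,
#'   `terminal_care_once`.
#' @param ae_costs named vector of per-event management costs.
#' @param ae_incidence list per arm of named incidence vectors; every AE
#'   named must have a cost in `ae_costs`.
#' @param utilities named vector with `pfs` and `pd`, each in `[0, 1]`.
#' @param accrual list with `followup`, `supportive_care` (each one of
#'   `"pfs"`, `"pd"`, `"alive"`) and `ae_mode` (`"per_cycle"` or `"once"`).
#' @return object of class `econ_inputs`.
#' @export
econ_inputs <- function(costs, ae_costs, ae_incidence, utilities,
                        accrual = list(followup = "alive",
                                       supportive_care = "pfs",
                                       ae_mode = "per_cycle")) {
  costs <- unlist(costs)
  need <- c("palbociclib_per_cycle", "fulvestrant_per_250mg",
            "followup_per_cycle", "administration_per_cycle",
            "supportive_care_per_cycle", "terminal_care_once")
  missing <- setdiff(need, names(costs))
  if (length(missing))
    stop("econ_inputs: missing cost field(s): ", paste(missing, collapse = ", "))
  ae_costs <- unlist(ae_costs)
  if (any(c(costs, ae_costs) < 0)) stop("econ_inputs: costs must be >= 0")
  ae_incidence <- lapply(ae_incidence, unlist)
  for (arm in names(ae_incidence)) {
    inc <- ae_incidence[[arm]]
    if (any(inc < 0 | inc > 1))
      stop("econ_inputs: ae_incidence must lie in [0, 1] (arm ", arm, ")")
    unknown <- setdiff(names(inc), names(ae_costs))
    if (length(unknown))
      stop("econ_inputs: no cost for AE(s): ", paste(unknown, collapse = ", "))
  }
  utilities <- unlist(utilities)
  if (!all(c("pfs", "pd") %in% names(utilities)))
    stop("econ_inputs: utilities must name 'pfs' and 'pd'")
  if (any(utilities < 0 | utilities > 1))
    stop("econ_inputs: utilities must lie in [0, 1]")
  if (!accrual$followup %in% c("pfs", "pd", "alive") ||
      !accrual$supportive_care %in% c("pfs", "pd", "alive"))
    stop("econ_inputs: accrual states must be 'pfs', 'pd' or 'alive'")
  if (!accrual$ae_mode %in% c("per_cycle", "once"))
    stop("econ_inputs: accrual$ae_mode must be 'per_cycle' or 'once'")
  structure(list(costs = costs[need], ae_costs = ae_costs,
                 ae_incidence = ae_incidence, utilities = utilities,
                 accrual = accrual),
            class = "econ_inputs")
}

#' Dosing schedule
#'
#' Palbociclib 125 mg daily for 21 of each 28-day cycle (priced per cycle);
#' fulvestrant 500 mg per administration (two 250 mg doses), administered
#' twice in cycle 1 (days 1 and 15, the loading schedule) and once per
#' cycle thereafter. Both drugs are given while progression-free only.
#'
#' @param fulvestrant_mg_per_admin mg per administration (500).
#' @param fulvestrant_vial_mg mg per priced unit (250).
#' @param fulvestrant_admins_cycle1 administrations in cycle 1 (2).
#' @param fulvestrant_admins_later administrations per later cycle (1).
#' @return object of class `dosing_schedule`.
#' @export
dosing_schedule <- function(fulvestrant_mg_per_admin = 500,
                            fulvestrant_vial_mg = 250,
                            fulvestrant_admins_cycle1 = 2,
                            fulvestrant_admins_later = 1) {
  if (!fulvestrant_admins_cycle1 %in% 1:2 || !fulvestrant_admins_later %in% 1:2)
    stop("dosing_schedule: administrations per cycle must be 1 or 2")
  vials <- fulvestrant_mg_per_admin / fulvestrant_vial_mg
  if (vials <= 0 || vials != round(vials))
    stop("dosing_schedule: administration dose must be a whole number of vials")
  structure(list(fulvestrant_mg_per_admin = fulvestrant_mg_per_admin,
                 fulvestrant_vial_mg = fulvestrant_vial_mg,
                 fulvestrant_vials_per_admin = vials,
                 fulvestrant_admins_cycle1 = fulvestrant_admins_cycle1,
                 fulvestrant_admins_later = fulvestrant_admins_later),
            class = "dosing_schedule")
}

#' Expected adverse-event management cost per patient
#'
#' Dot product of the arm's grade >= 3 AE incidences and the per-event
#' management costs. This is the amount charged once at entry under
#' `ae_mode = "once"`, or accrued per cycle of PFS membership under
#' `ae_mode = "per_cycle"`.
#'
#' @param inputs an [econ_inputs()].
#' @param arm arm name, must exist in `inputs$ae_incidence`.
#' @export
ae_expected_cost <- function(inputs, arm) {
  stopifnot(inherits(inputs, "econ_inputs"))
  if (!arm %in% names(inputs$ae_incidence))
    stop("ae_expected_cost: unknown arm '", arm, "'")
  inc <- inputs$ae_incidence[[arm]]
  sum(inc * inputs$ae_costs[names(inc)])
}

#' One-off adverse-event cost at model entry
#'
#' The incidence-weighted AE cost applied once in cycle 1 and discounted at
#' the cycle-1 factor (the `ae_mode = "once"` accrual).
#'
#' @inheritParams ae_expected_cost
#' @param settings a [model_settings()].
#' @export
ae_one_off_cost <- function(inputs, arm, settings) {
  ae_expected_cost(inputs, arm) * discount_factor(settings, 1)
}

state_credit <- function(credits, state) {
  switch(state,
    pfs = credits[, "pfs"],
    pd = credits[, "pd"],
    alive = credits[, "pfs"] + credits[, "pd"])
}

#' Discounted costs over a corrected trace
#'
#' Accumulates all cost categories per cycle under the accrual rules of
#' [econ_inputs()], discounts at the per-cycle factor, and sums.
#'
#' @param credits a [half_cycle_correct()] result.
#' @param inputs an [econ_inputs()].
#' @param schedule a [dosing_schedule()].
#' @param settings a [model_settings()].
#' @param arm arm name (keyed into `inputs$ae_incidence`).
#' @param include_palbociclib does this arm receive palbociclib?
#' @return list with `total` (USD) and `breakdown` (named vector summing to
#'   `total`).
#' @export
cycle_costs <- function(credits, inputs, schedule, settings, arm,
                        include_palbociclib = identical(arm, "palbociclib")) {
  stopifnot(inherits(credits, "cohort_credits"), inherits(inputs, "econ_inputs"),
            inherits(schedule, "dosing_schedule"), inherits(settings, "model_settings"))
  n <- nrow(credits)
  if (any(credits < -1e-12)) stop("cycle_costs: negative state membership")
  disc <- discount_factor(settings, seq_len(n))
  pfs_c <- credits[, "pfs"]
  new_deaths <- attr(credits, "new_deaths")
  cost <- inputs$costs

  admins <- c(schedule$fulvestrant_admins_cycle1,
              rep(schedule$fulvestrant_admins_later, n - 1))
  fulv_per_cycle <- admins * schedule$fulvestrant_vials_per_admin *
    cost[["fulvestrant_per_250mg"]]

  palbo <- if (include_palbociclib)
    sum(cost[["palbociclib_per_cycle"]] * pfs_c * disc) else 0
  fulv <- sum(fulv_per_cycle * pfs_c * disc)
  admin <- sum(cost[["administration_per_cycle"]] * pfs_c * disc)
  fu <- sum(cost[["followup_per_cycle"]] *
            state_credit(credits, inputs$accrual$followup) * disc)
  sc <- sum(cost[["supportive_care_per_cycle"]] *
            state_credit(credits, inputs$accrual$supportive_care) * disc)
  term <- sum(cost[["terminal_care_once"]] * new_deaths * disc)
  ae_unit <- ae_expected_cost(inputs, arm)
  ae <- if (inputs$accrual$ae_mode == "per_cycle")
    sum(ae_unit * pfs_c * disc) else ae_unit * disc[1]

  breakdown <- c(palbociclib = palbo, fulvestrant = fulv,
                 administration = admin, followup = fu,
                 supportive_care = sc, adverse_events = ae,
                 terminal_care = term)
  list(total = sum(breakdown), breakdown = breakdown)
}

#' Discounted QALYs over a corrected trace
#'
#' Per cycle, utility-weighted credited membership scaled to year fractions
#' (`cycle_length_days / 365.25`) and discounted.
#'
#' @inheritParams cycle_costs
#' @return total discounted QALYs (numeric).
#' @export
cycle_qalys <- function(credits, inputs, settings) {
  stopifnot(inherits(credits, "cohort_credits"), inherits(inputs, "econ_inputs"),
            inherits(settings, "model_settings"))
  n <- nrow(credits)
  disc <- discount_factor(settings, seq_len(n))
  u <- inputs$utilities
  sum((u[["pfs"]] * credits[, "pfs"] + u[["pd"]] * credits[, "pd"]) *
        settings$cycle_years * disc)
}

#' Run one arm end to end
#'
#' Builds transitions from the arm's PFS/OS models, runs and corrects the
#' cohort trace, and accumulates discounted costs and QALYs.
#'
#' @param pfs_model,os_model [surv_model()] objects for the arm.
#' @param inputs an [econ_inputs()].
#' @param schedule a [dosing_schedule()].
#' @param settings a [model_settings()].
#' @param arm arm name.
#' @param include_palbociclib does this arm receive palbociclib?
#' @return an `arm_outcome`: list with `arm`, `total_cost`, `total_qaly`,
#'   `cost_breakdown`, `trace`, `credits`.
#' @export
run_arm <- function(pfs_model, os_model, inputs, schedule, settings, arm,
                    include_palbociclib = identical(arm, "palbociclib")) {
  trans <- build_transitions(pfs_model, os_model, settings)
  trace <- run_cohort(trans, settings)
  credits <- half_cycle_correct(trace)
  costs <- cycle_costs(credits, inputs, schedule, settings, arm,
                       include_palbociclib = include_palbociclib)
  structure(list(arm = arm, total_cost = costs$total,
                 total_qaly = cycle_qalys(credits, inputs, settings),
                 cost_breakdown = costs$breakdown,
                 trace = trace, credits = credits),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome: %s | cost $%.2f, %.4f QALYs>\n",
              x$arm, x$total_cost, x$total_qaly))
  invisible(x)
}

#' Incremental comparison of two arms
#'
#' @param a,b `arm_outcome` objects (intervention and comparator) computed
#'   under identical settings.
#' @return a `comparison`: list with `delta_cost`, `delta_qaly`, `icer`
#'   (NA when undefined) and `dominance` (`"none"`, `"dominant"` = cheaper
#'   and more effective, `"dominated"` = costlier and less effective, or
#'   `"undefined"` when `delta_qaly` is 0).
#' @export
compare <- function(a, b) {
  stopifnot(inherits(a, "arm_outcome"), inherits(b, "arm_outcome"))
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qaly - b$total_qaly
  if (dq == 0) {
    icer <- NA_real_; dom <- "undefined"
  } else if (dc < 0 && dq > 0) {
    icer <- NA_real_; dom <- "dominant"
  } else if (dc > 0 && dq < 0) {
    icer <- NA_real_; dom <- "dominated"
  } else {
    icer <- dc / dq; dom <- "none"
  }
  structure(list(intervention = a$arm, comparator = b$arm,
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 dominance = dom),
            class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("<comparison: %s vs %s | dC $%.2f, dE %.4f QALYs, %s>\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) x$dominance else sprintf("ICER $%.2f/QALY", x$icer)))
  invisible(x)
}
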