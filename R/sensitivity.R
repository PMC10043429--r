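# One-way deterministic sensitivity analysis (tornado) and Monte-Carlo
# probabilistic sensitivity analysis (scatter + CEAC).

#' Table of uncertain parameters
#'
#' Flattens the configuration's uncertain inputs into one row per scalar
#' parameter: dotted `name` (usable with [apply_overrides()]), display
#' `label`, DSA `group`, `base`/`lower`/`upper`, `distribution`, and a
#' `scenario` flag.
#'
#' Grouping conventions (see the methods vignette):
#' * each adverse event forms one DSA group ("Cost of <AE>") containing its
#'   management cost and its incidence(s); the tornado moves the whole
#'   group to its bounds jointly, so one bar reflects that AE's total cost
#'   uncertainty;
#' * the discount rate is flagged `scenario = TRUE`: it is varied in the
#'   DSA and sampled in the PSA (Normal, per its configured distribution)
#'   but excluded from the tornado ranking of input uncertainties.
#'
#' @param config a `cea_config`.
#' @return data frame with columns `name`, `label`, `group`, `base`,
#'   `lower`, `upper`, `distribution`, `scenario`.
#' @export
parameter_table <- function(config) {
  rows <- list()
  add <- function(name, label, group, spec, scenario = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, label = label, group = group, base = spec$base,
      lower = spec$lower, upper = spec$upper,
      distribution = spec$distribution, scenario = scenario,
      stringsAsFactors = FALSE)
  }
  cost_labels <- c(palbociclib_per_cycle = "Cost of palbociclib",
                   fulvestrant_per_250mg = "Cost of fulvestrant",
                   followup_per_cycle = "Cost of follow-up",
                   administration_per_cycle = "Cost of drug administration",
                   supportive_care_per_cycle = "Cost of supportive care",
                   terminal_care_once = "Cost of terminal care")
  for (field in names(config$costs)) {
    lab <- if (field %in% names(cost_labels)) cost_labels[[field]]
           else paste("Cost of", field)
    add(paste0("costs.", field), lab, lab, config$costs[[field]])
  }
  for (ae in names(config$ae_costs)) {
    group <- paste0("Cost of ", ae)
    add(paste0("ae_costs.", ae), group, group, config$ae_costs[[ae]])
    for (arm in names(config$ae_incidence))
      if (ae %in% names(config$ae_incidence[[arm]]))
        add(paste0("ae_incidence.", arm, ".", ae),
            sprintf("Incidence of %s (%s)", ae, arm), group,
            config$ae_incidence[[arm]][[ae]])
  }
  add("utilities.pfs", "Utility of PFS", "Utility of PFS", config$utilities$pfs)
  add("utilities.pd", "Utility of PD", "Utility of PD", config$utilities$pd)
  add("model.discount_rate", "Discount rate", "Discount rate",
      config$model$discount_rate, scenario = TRUE)
  do.call(rbind, rows)
}

#' Moment-matched sampling distribution for one parameter
#'
#' Maps `base`, `lower`, `upper` and a family tag to a sampler. The bounds
#' are read as a 95% interval, `sd = (upper - lower) / (2 * 1.96)`; Gamma
#' and Beta are moment-matched to `mean = base` and that sd
#' (`shape = (m/sd)^2`, `rate = m/sd^2`; Beta via
#' `alpha + beta = m(1-m)/sd^2 - 1`), Normal uses them directly. A zero sd
#' yields a degenerate point mass.
#'
#' @param base,lower,upper base value and bounds.
#' @param distribution `"gamma"`, `"beta"`, `"normal"` or `"fixed"`.
#' @return list with `distribution`, `mean`, `sd`, family parameters, and
#'   a `sample(n)` function.
#' @export
parameterize_distribution <- function(base, lower, upper,
                                      distribution = c("gamma", "beta",
                                                       "normal", "fixed")) {
  distribution <- match.arg(distribution)
  sdev <- (upper - lower) / (2 * 1.96)
  if (distribution == "fixed" || sdev == 0)
    return(list(distribution = "fixed", mean = base, sd = 0,
                sample = function(n) rep(base, n)))
  out <- list(distribution = distribution, mean = base, sd = sdev)
  if (distribution == "gamma") {
    if (base <= 0) stop("parameterize_distribution: gamma needs a positive mean")
    out$shape <- (base / sdev)^2
    out$rate <- base / sdev^2
    out$sample <- function(n) stats::rgamma(n, shape = out$shape, rate = out$rate)
  } else if (distribution == "beta") {
    if (base <= 0 || base >= 1)
      stop("parameterize_distribution: beta needs a mean in (0, 1)")
    ab <- base * (1 - base) / sdev^2 - 1
    if (ab <= 0)
      stop("parameterize_distribution: beta bounds too wide for the mean")
    out$alpha <- base * ab
    out$beta <- (1 - base) * ab
    out$sample <- function(n) stats::rbeta(n, out$alpha, out$beta)
  } else {
    out$sample <- function(n) stats::rnorm(n, base, sdev)
  }
  out
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full two-arm pipeline with each parameter group set to its
#' lower and then its upper bound, all other parameters at base. Grouped
#' rows (an AE's cost and incidences) move to their bounds together. A
#' bound that makes the model invalid is recorded as a failed bound
#' (NA with a note), not an error.
#'
#' @param config a `cea_config`.
#' @param table parameter table, defaults to [parameter_table()].
#' @return a `dsa_result` data frame: `group`, `scenario`, `icer_at_lower`,
#'   `icer_at_upper`, `range_width`, `note`; attribute `base_icer`.
#' @export
one_way_dsa <- function(config, table = parameter_table(config)) {
  base_icer <- evaluate_config(config)$comparison$icer
  icer_at <- function(rows, bound) {
    ov <- stats::setNames(rows[[bound]], rows$name)
    tryCatch(evaluate_config(config, ov)$comparison$icer,
             error = function(e) structure(NA_real_, msg = conditionMessage(e)))
  }
  groups <- unique(table$group)
  res <- lapply(groups, function(g) {
    rows <- table[table$group == g, , drop = FALSE]
    lo <- icer_at(rows, "lower")
    hi <- icer_at(rows, "upper")
    note <- c(attr(lo, "msg"), attr(hi, "msg"))
    data.frame(group = g, scenario = all(rows$scenario),
               icer_at_lower = as.numeric(lo), icer_at_upper = as.numeric(hi),
               range_width = abs(as.numeric(hi) - as.numeric(lo)),
               note = if (length(note)) paste(note, collapse = "; ") else "",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, res), base_icer = base_icer,
            class = c("dsa_result", "data.frame"))
}

#' Tornado ordering of a DSA result
#'
#' Parameters sorted by decreasing ICER range width; ties broken by group
#' name (lexicographic, C collation) so the ordering is deterministic and
#' invariant to input order. Scenario rows (discount rate) are excluded
#' unless `include_scenario = TRUE`.
#'
#' @param result a [one_way_dsa()] result.
#' @param include_scenario keep scenario rows in the ranking?
#' @return the reordered `dsa_result`.
#' @export
tornado_rank <- function(result, include_scenario = FALSE) {
  stopifnot(inherits(result, "dsa_result"))
  if (!nrow(result)) stop("tornado_rank: empty DSA result")
  if (!include_scenario) result <- result[!result$scenario, , drop = FALSE]
  old <- Sys.getlocale("LC_COLLATE"); on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  out <- result[order(-result$range_width, result$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte Carlo over all uncertain parameters: every parameter is
#' drawn independently from its moment-matched distribution
#' ([parameterize_distribution()]) and the full two-arm pipeline is re-run
#' per draw. Draws violating model constraints (utility of PD above
#' utility of PFS, negative discount rate) are resampled and counted.
#' Survival-model parameters are held fixed (no uncertainty is published
#' for them).
#'
#' @param config a `cea_config`.
#' @param n_draws number of Monte Carlo draws (default from `config$psa`).
#' @param seed RNG seed (default from `config$psa`); same seed, same draws.
#' @param table parameter table, defaults to [parameter_table()].
#' @return a `psa_result` data frame with per-draw arm totals,
#'   `delta_cost`, `delta_qaly`; attributes `seed`, `n_resampled`,
#'   `samples` (draws x parameters matrix).
#' @export
run_psa <- function(config, n_draws = config$psa$n_draws,
                    seed = config$psa$seed, table = parameter_table(config)) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  dists <- lapply(seq_len(nrow(table)), function(i)
    parameterize_distribution(table$base[i], table$lower[i], table$upper[i],
                              table$distribution[i]))
  names(dists) <- table$name
  i_upfs <- match("utilities.pfs", table$name)
  i_upd <- match("utilities.pd", table$name)
  i_disc <- match("model.discount_rate", table$name)
  n_resampled <- 0L

  draw_params <- function() {
    v <- vapply(dists, function(d) d$sample(1), numeric(1))
    for (guard in 1:100) {
      bad <- FALSE
      if (!is.na(i_disc) && v[i_disc] < 0) {
        v[i_disc] <- dists[[i_disc]]$sample(1); bad <- TRUE
      }
      if (!is.na(i_upfs) && !is.na(i_upd) && v[i_upd] > v[i_upfs]) {
        v[i_upfs] <- dists[[i_upfs]]$sample(1)
        v[i_upd] <- dists[[i_upd]]$sample(1)
        bad <- TRUE
      }
      if (!bad) return(v)
      n_resampled <<- n_resampled + 1L
    }
    stop("run_psa: could not draw a valid parameter set in 100 attempts")
  }

  samples <- matrix(NA_real_, n_draws, nrow(table),
                    dimnames = list(NULL, table$name))
  arm_names <- names(config$arms)[1:2]
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    v <- draw_params()
    samples[i, ] <- v
    res <- evaluate_config(config, v)
    cmp <- res$comparison
    rows[[i]] <- data.frame(
      draw = i,
      cost_a = res[[arm_names[1]]]$total_cost,
      cost_b = res[[arm_names[2]]]$total_cost,
      qaly_a = res[[arm_names[1]]]$total_qaly,
      qaly_b = res[[arm_names[2]]]$total_qaly,
      delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly)
  }
  out <- do.call(rbind, rows)
  structure(out, seed = seed, n_resampled = n_resampled, samples = samples,
            arms = arm_names, class = c("psa_result", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit, `delta_qaly * wtp - delta_cost > 0`.
#'
#' @param psa a [run_psa()] result (or any data frame with `delta_cost`
#'   and `delta_qaly`).
#' @param wtp_grid WTP grid in USD/QALY (default $0-120,000 by $500).
#' @return data frame with `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 120000, by = 500)) {
  if (!nrow(psa)) stop("ceac: empty PSA sample")
  prob <- vapply(wtp_grid, function(w)
    mean(psa$delta_qaly * w - psa$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' First WTP at which the CEAC reaches a probability
#'
#' @param curve a [ceac()] data frame.
#' @param level probability level (default 0.5).
#' @return the WTP, or NA if never reached on the grid.
#' @export
ceac_crossing <- function(curve, level = 0.5) {
  hit <- which(curve$probability >= level)
  if (!length(hit)) NA_real_ else curve$wtp[hit[1]]
}
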