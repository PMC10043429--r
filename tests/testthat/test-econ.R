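# single-cycle toy model: whole cohort progression-free through one cycle,
# no deaths, no discounting
toy_context <- function(discount = 0) {
  s <- model_settings(horizon_years = 28.5 / 365.25, background_mortality = 0,
                      discount_rate_annual = discount)
  ex <- surv_model("exponential", rate = 1e-15)
  credits <- half_cycle_correct(run_cohort(build_transitions(ex, ex, s), s))
  list(settings = s, credits = credits)
}

test_that("drug costs follow the dosing schedule", {
  ctx <- toy_context()
  inputs <- config_inputs(base_cfg)
  schedule <- config_schedule(base_cfg)
  expect_identical(schedule$fulvestrant_vials_per_admin, 2)

  costs <- cycle_costs(ctx$credits, inputs, schedule, ctx$settings,
                       "palbociclib")
  # cycle 1 carries the fulvestrant loading dose: 2 administrations x 2 vials
  expect_equal(costs$breakdown[["fulvestrant"]], 2 * 2 * 287.90)
  expect_equal(costs$breakdown[["palbociclib"]], 640.39)
  expect_equal(costs$breakdown[["administration"]], 33.56)
  expect_equal(costs$breakdown[["terminal_care"]], 0)

  placebo <- cycle_costs(ctx$credits, inputs, schedule, ctx$settings, "placebo")
  expect_equal(placebo$breakdown[["palbociclib"]], 0)
})

test_that("adverse-event costs are the incidence-weighted sums", {
  inputs <- config_inputs(base_cfg)
  expect_equal(ae_expected_cost(inputs, "palbociclib"),
               0.577 * 412 + 0.377 * 435.58 + 0.046 * 395.82 +
                 0.029 * 110 + 0.006 * 323, tolerance = 1e-12)
  expect_equal(ae_expected_cost(inputs, "palbociclib"), 425.27338,
               tolerance = 1e-7)
  expect_equal(ae_expected_cost(inputs, "placebo"), 19.72518,
               tolerance = 1e-7)
  expect_error(ae_expected_cost(inputs, "nivolumab"), "unknown arm")

  s <- model_settings()
  expect_equal(ae_one_off_cost(inputs, "placebo", s),
               19.72518 * discount_factor(s, 1), tolerance = 1e-6)
})

test_that("zero-cost inputs give zero total cost", {
  ctx <- toy_context()
  inputs <- config_inputs(base_cfg)
  inputs$costs[] <- 0
  inputs$ae_costs[] <- 0
  costs <- cycle_costs(ctx$credits, inputs, config_schedule(base_cfg),
                       ctx$settings, "palbociclib")
  expect_identical(costs$total, 0)
})

test_that("QALYs scale utility-weighted person-time into years", {
  ctx <- toy_context()
  inputs <- config_inputs(base_cfg)

  u1 <- inputs; u1$utilities[] <- c(1, 1)
  person_years <- sum(ctx$credits[, c("pfs", "pd")]) * ctx$settings$cycle_years
  expect_equal(cycle_qalys(ctx$credits, u1, ctx$settings), person_years)

  u0 <- inputs; u0$utilities[] <- c(0, 0)
  expect_identical(cycle_qalys(ctx$credits, u0, ctx$settings), 0)

  # all progression-free: QALYs = u_pfs x person-years
  expect_equal(cycle_qalys(ctx$credits, inputs, ctx$settings),
               0.87 * person_years, tolerance = 1e-12)
})

test_that("cost breakdown always sums to the total", {
  res <- evaluate_config(base_cfg)
  for (arm in c("palbociclib", "placebo")) {
    expect_lt(abs(sum(res[[arm]]$cost_breakdown) - res[[arm]]$total_cost), 1e-6)
    expect_gte(res[[arm]]$total_qaly, 0)
  }
})

test_that("incremental comparison computes exact deltas and flags dominance", {
  res <- evaluate_config(base_cfg)
  cmp <- res$comparison
  expect_identical(cmp$delta_cost,
                   res$palbociclib$total_cost - res$placebo$total_cost)
  expect_identical(cmp$delta_qaly,
                   res$palbociclib$total_qaly - res$placebo$total_qaly)
  expect_identical(cmp$icer, cmp$delta_cost / cmp$delta_qaly)

  expect_identical(compare(res$palbociclib, res$palbociclib)$dominance,
                   "undefined")
  cheap_win <- res$palbociclib
  cheap_win$total_cost <- res$placebo$total_cost - 1
  expect_identical(compare(cheap_win, res$placebo)$dominance, "dominant")
  expect_identical(compare(res$placebo, cheap_win)$dominance, "dominated")
})

test_that("costs and QALYs respond monotonically to their inputs", {
  base <- evaluate_config(base_cfg)
  up <- evaluate_config(base_cfg, c(costs.palbociclib_per_cycle = 700))
  expect_gt(up$palbociclib$total_cost, base$palbociclib$total_cost)
  expect_identical(up$placebo$total_cost, base$placebo$total_cost)

  hu <- evaluate_config(base_cfg, c(utilities.pfs = 0.95))
  expect_gt(hu$palbociclib$total_qaly, base$palbociclib$total_qaly)
})

test_that("total costs are equivariant under currency rescaling", {
  tab <- parameter_table(base_cfg)
  cost_rows <- tab[tab$distribution == "gamma", ]
  doubled <- setNames(cost_rows$base * 2, cost_rows$name)
  base <- evaluate_config(base_cfg)
  twice <- evaluate_config(base_cfg, doubled)
  for (arm in c("palbociclib", "placebo")) {
    expect_equal(twice[[arm]]$total_cost, 2 * base[[arm]]$total_cost,
                 tolerance = 1e-10)
    expect_identical(twice[[arm]]$total_qaly, base[[arm]]$total_qaly)
  }
  expect_equal(twice$comparison$icer, 2 * base$comparison$icer,
               tolerance = 1e-10)
})

test_that("discounting never increases a non-negative payoff stream", {
  undisc <- evaluate_config(base_cfg, c(model.discount_rate = 0))
  disc <- evaluate_config(base_cfg)
  for (arm in c("palbociclib", "placebo")) {
    expect_lt(disc[[arm]]$total_cost, undisc[[arm]]$total_cost)
    expect_lt(disc[[arm]]$total_qaly, undisc[[arm]]$total_qaly)
  }
})
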