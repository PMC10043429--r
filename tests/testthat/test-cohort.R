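test_that("model settings derive cycle counts and conversions correctly", {
  s <- model_settings()
  expect_identical(s$n_cycles, 130L)
  expect_equal(s$background_mortality_cycle, 0.00718)

  s_annual <- model_settings(background_mortality_timescale = "annual")
  expect_equal(s_annual$background_mortality_cycle, 5.522504844e-4,
               tolerance = 1e-9)
  expect_equal(annual_to_cycle_prob(0.00718, 28),
               1 - (1 - 0.00718)^(28 / 365.25), tolerance = 1e-15)
  expect_error(model_settings(discount_rate_annual = 1.5), "discount")
  expect_error(model_settings(horizon_years = 0.01), "horizon")
})

test_that("discounting compounds the annual rate over cycle time", {
  s <- model_settings()
  expect_identical(discount_factor(s, 0), 1)
  r_cycle <- 1 / discount_factor(s, 1) - 1
  expect_equal(r_cycle, 1.05^(28 / 365.25) - 1, tolerance = 1e-15)
  expect_equal(r_cycle, 0.003747248749, tolerance = 1e-9)
  # one year of cycles discounts by exactly one annual factor
  expect_equal(discount_factor(s, 365.25 / 28), 1 / 1.05, tolerance = 1e-12)
})

test_that("transition matrices are row-stochastic with absorbing death", {
  s <- model_settings()
  for (arm in c("palbociclib", "placebo")) {
    tr <- build_transitions(config_surv(base_cfg, arm, "pfs"),
                            config_surv(base_cfg, arm, "os"), s)
    rs <- apply(tr, 3, rowSums)
    expect_true(all(abs(rs - 1) < 1e-12))
    expect_true(all(tr >= 0 & tr <= 1))
    expect_true(all(tr[3, 3, ] == 1))
    expect_true(all(tr[3, 1:2, ] == 0))
    # PFS->Death carries the per-cycle background mortality
    expect_true(all(tr[1, 3, ] == s$background_mortality_cycle))
    # PFS->PFS implies a non-increasing PFS survival
    expect_true(all(diff(cumprod(tr[1, 1, ])) <= 0))
  }
})

test_that("annualized background mortality reproduces the converted split", {
  s <- model_settings(background_mortality_timescale = "annual")
  tr <- build_transitions(config_surv(base_cfg, "placebo", "pfs"),
                          config_surv(base_cfg, "placebo", "os"), s)
  expect_equal(unname(tr[1, , 1]), c(0.868924, 0.130524, 0.000552),
               tolerance = 1e-5)
})

test_that("cohort traces conserve probability and absorb monotonically", {
  s <- model_settings()
  for (arm in c("palbociclib", "placebo")) {
    tr <- build_transitions(config_surv(base_cfg, arm, "pfs"),
                            config_surv(base_cfg, arm, "os"), s)
    trace <- run_cohort(tr, s)
    expect_equal(unname(trace[1, ]), c(1, 0, 0))
    expect_true(all(abs(rowSums(trace) - 1) < 1e-10))
    expect_true(all(diff(trace[, "death"]) >= -1e-15))
    expect_true(all(diff(trace[, "pfs"]) <= 1e-15))
  }
})

test_that("run_cohort handles degenerate transition sequences", {
  s <- model_settings()
  # (near-)identity transitions freeze the cohort in PFS
  ex <- surv_model("exponential", rate = 1e-15)
  s0 <- model_settings(background_mortality = 0)
  trace <- run_cohort(build_transitions(ex, ex, s0), s0)
  expect_equal(unname(trace[131, ]), c(1, 0, 0), tolerance = 1e-10)

  # fully absorbing first transition sends everyone to death in one cycle
  arr <- array(0, dim = c(3, 3, 130),
               dimnames = list(c("pfs", "pd", "death"),
                               c("pfs", "pd", "death"), NULL))
  arr[, 3, ] <- 1
  arr <- structure(arr, class = c("transition_array", "array"))
  trace <- run_cohort(arr, s)
  expect_equal(unname(trace[2, ]), c(0, 0, 1))

  short <- build_transitions(ex, ex, s0)[, , 1:10, drop = FALSE]
  short <- structure(short, class = c("transition_array", "array"))
  expect_error(run_cohort(short, s), "cover")
})

test_that("half-cycle correction is the trapezoid of the trace", {
  s <- model_settings()
  tr <- build_transitions(config_surv(base_cfg, "placebo", "pfs"),
                          config_surv(base_cfg, "placebo", "os"), s)
  trace <- run_cohort(tr, s)
  cred <- half_cycle_correct(trace)
  expect_equal(nrow(cred), 130)
  expect_equal(cred[1, "pfs"], (trace[1, "pfs"] + trace[2, "pfs"]) / 2)
  # a constant column is unchanged; a 1 -> 0 drop credits one half
  expect_equal(unname(cred[, "pfs"] + cred[, "pd"] + cred[, "death"]),
               rep(1, 130), tolerance = 1e-10)
  expect_equal(sum(attr(cred, "new_deaths")), trace[131, "death"],
               tolerance = 1e-12)
})

test_that("credited person-cycles approximate the restricted mean survival", {
  # with zero background mortality the PFS column equals the Weibull
  # survival curve, so trapezoid credits ~ its integral over the horizon
  s0 <- model_settings(background_mortality = 0)
  pfs <- config_surv(base_cfg, "palbociclib", "pfs")
  os <- config_surv(base_cfg, "palbociclib", "os")
  cred <- half_cycle_correct(run_cohort(build_transitions(pfs, os, s0), s0))
  rmst <- integrate(function(t) survival_at(pfs, t), 0, 130,
                    rel.tol = 1e-10)$value
  expect_lt(abs(sum(cred[, "pfs"]) - rmst), 0.5)  # within one half-cycle
})

test_that("with instant progression the model reproduces the OS curve", {
  s0 <- model_settings(background_mortality = 0)
  fast <- surv_model("exponential", rate = 50)   # PFS exits immediately
  os <- config_surv(base_cfg, "placebo", "os")
  trace <- run_cohort(build_transitions(fast, os, s0), s0)
  # OS mortality applies from PD onward, so the death column follows the
  # OS curve conditional on surviving the (instant) progression cycle
  t <- 1:130
  expected <- 1 - survival_at(os, t) / survival_at(os, 1)
  expect_lt(max(abs(trace[t + 1, "death"] - expected)), 1e-6)
})
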