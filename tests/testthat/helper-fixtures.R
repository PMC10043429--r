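# Shared fixtures: the shipped base-case configuration and the published
# point estimates its results are checked against.

base_cfg <- load_config(base_config_path())

published <- list(
  cost_palbo = 55482.06, cost_placebo = 19342.12,
  qaly_palbo = 2.56, qaly_placebo = 1.90,
  delta_cost = 36139.94, delta_qaly = 0.65, icer = 55224.90,
  wtp = 34138.28, ceac50 = 59581.59, ceac100 = 78048.90)

# one surv_model per family with plausible parameters, for property loops
family_examples <- function(seed = 123) {
  set.seed(seed)
  list(
    surv_model("weibull", shape = runif(1, 0.5, 2), scale = runif(1, 0.01, 0.3)),
    surv_model("exponential", rate = runif(1, 0.01, 0.3)),
    surv_model("lognormal", meanlog = runif(1, 1, 3), sdlog = runif(1, 0.3, 1.5)),
    surv_model("loglogistic", shape = runif(1, 0.8, 3), scale = runif(1, 5, 40)),
    surv_model("gompertz", shape = runif(1, 0.01, 0.2), rate = runif(1, 0.005, 0.1)),
    surv_model("generalized_gamma", mu = runif(1, 1, 3),
               sigma = runif(1, 0.4, 1.5), Q = runif(1, -1, 1.5)))
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
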