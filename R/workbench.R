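# End-to-end analysis driver: base case + DSA + PSA + CEAC, written as CSV
# artifacts with a checksummed index and a reproduction log.

write_artifact <- function(df, dir, file) {
  path <- file.path(dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the complete analysis and write all artifacts
#'
#' Executes the base case, the one-way DSA with tornado ranking, and the
#' PSA with CEAC, and writes every table as CSV under `out_dir`, together
#' with a plain-text summary, a machine-readable `index.csv` listing each
#' artifact with its md5 checksum, and `run_log.txt` recording the seed,
#' configuration hash, cycle count and stage timings. Identical config and
#' seed give identical artifacts. If a stage fails, completed artifacts are
#' kept and an `error_manifest.txt` names the failed stage.
#'
#' @param config a `cea_config`.
#' @param out_dir output directory (created if needed).
#' @param n_draws,seed PSA settings (default from `config$psa`).
#' @param wtp_grid CEAC grid (default $0-120,000 by $500).
#' @return (invisibly) list with `base_case`, `dsa`, `tornado`, `psa`,
#'   `ceac`, `index`.
#' @export
run_full_analysis <- function(config, out_dir,
                              n_draws = config$psa$n_draws,
                              seed = config$psa$seed,
                              wtp_grid = seq(0, 120000, by = 500)) {
  stopifnot(inherits(config, "cea_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character(0)
  timings <- character(0)
  failures <- character(0)

  stage <- function(name, fun) {
    s <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
    timings <<- c(timings, sprintf("%-10s %.2f s", name,
                                   as.numeric(Sys.time() - s, units = "secs")))
    out
  }

  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  settings <- config_settings(config)

  base <- stage("base_case", function() {
    bc <- run_base_case(config)
    arms <- Filter(function(e) inherits(e, "arm_outcome"), bc)
    tab <- do.call(rbind, lapply(arms, function(a)
      data.frame(arm = a$arm, cost = a$total_cost, qaly = a$total_qaly)))
    cmp <- bc$comparison
    tab$delta_cost <- c(cmp$delta_cost, NA)
    tab$delta_qaly <- c(cmp$delta_qaly, NA)
    tab$icer <- c(cmp$icer, NA)
    files <<- c(files, write_artifact(tab, out_dir, "base_case.csv"))
    brk <- do.call(rbind, lapply(arms, function(a)
      data.frame(arm = a$arm, category = names(a$cost_breakdown),
                 cost = unname(a$cost_breakdown))))
    files <<- c(files, write_artifact(brk, out_dir, "cost_breakdown.csv"))
    for (a in arms)
      files <<- c(files, write_artifact(trace_as_df(a$trace), out_dir,
                                        sprintf("trace_%s.csv", a$arm)))
    files <<- c(files, write_artifact(bc$verdicts, out_dir, "verdicts.csv"))
    bc
  })

  dsa <- stage("dsa", function() {
    d <- one_way_dsa(config)
    files <<- c(files, write_artifact(as.data.frame(d), out_dir, "dsa.csv"))
    d
  })
  tornado <- if (!is.null(dsa)) stage("tornado", function() {
    r <- tornado_rank(dsa)
    files <<- c(files, write_artifact(as.data.frame(r), out_dir, "tornado.csv"))
    r
  }) else NULL

  psa <- stage("psa", function() {
    p <- run_psa(config, n_draws = n_draws, seed = seed)
    files <<- c(files, write_artifact(as.data.frame(p), out_dir, "psa_draws.csv"))
    p
  })
  cc <- if (!is.null(psa)) stage("ceac", function() {
    cv <- ceac(psa, wtp_grid)
    files <<- c(files, write_artifact(cv, out_dir, "ceac.csv"))
    cv
  }) else NULL

  summary_path <- file.path(out_dir, "summary.txt")
  con <- file(summary_path, "w")
  writeLines(c("palboCEA analysis summary",
               sprintf("config md5: %s", cfg_hash),
               sprintf("seed: %s  psa draws: %d", format(seed), n_draws),
               sprintf("cycles: %d x %g days, horizon %g years",
                       settings$n_cycles, settings$cycle_length_days,
                       settings$horizon_years), ""), con)
  if (!is.null(base)) {
    sink(con); print(base); sink()
  }
  if (!is.null(tornado) && nrow(tornado)) {
    writeLines(c("", "Tornado ranking (ICER range width, USD/QALY):"), con)
    writeLines(sprintf("  %-28s %10.2f", tornado$group, tornado$range_width), con)
  }
  if (!is.null(cc)) {
    writeLines(c("", sprintf("CEAC 50%% crossover: $%s/QALY",
                             format(ceac_crossing(cc, 0.5)))), con)
    for (w in unlist(config$wtp_thresholds))
      writeLines(sprintf("P(cost-effective) at WTP $%.2f: %.3f", w,
                         mean(psa$delta_qaly * w - psa$delta_cost > 0)), con)
  }
  close(con)
  files <- c(files, summary_path)

  if (length(failures))
    writeLines(failures, file.path(out_dir, "error_manifest.txt"))

  index <- data.frame(file = basename(files),
                      md5 = unname(tools::md5sum(files)),
                      row.names = NULL)
  utils::write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE)

  writeLines(c(sprintf("run started: %s", format(t0)),
               sprintf("config md5: %s", cfg_hash),
               sprintf("seed: %s", format(seed)),
               sprintf("n_cycles: %d", settings$n_cycles),
               timings,
               if (length(failures)) c("FAILURES:", failures) else "status: ok"),
             file.path(out_dir, "run_log.txt"))

  invisible(list(base_case = base, dsa = dsa, tornado = tornado,
                 psa = psa, ceac = cc, index = index))
}
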