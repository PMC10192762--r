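## End-to-end pipeline: generate fixtures -> calibrate -> scan -> separatrix ->
## switch curves -> cohort envelopes -> phenotype calls -> summary report.

#' Write a trajectory as tidy CSV
#'
#' Columns `time_months`, `IGF1_ng_ml`, `IL6_pg_ml` and, for full-system
#' trajectories, `M`, `MD`, `D`.
#'
#' @param traj a `frailty_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "frailty_trajectory"))
  df <- data.frame(time_months = traj$time, IGF1_ng_ml = traj$IGF1,
                   IL6_pg_ml = traj$IL6)
  for (cn in intersect(c("M", "MD", "D"), names(traj))) df[[cn]] <- traj[[cn]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All constants default to the literature values the model is built around
#' (physiological maxima 400 ng/ml and 25 pg/ml; baselines 107.8 ng/ml and
#' 3.14 pg/ml; annual trends -1.95 ng/ml and +0.05 pg/ml; extreme-cohort
#' mortality ratio 2.5; k_extra 2.5; 240-month longevity horizon). Resolutions
#' are pipeline choices.
#'
#' @param ... named overrides of any default.
#' @return A configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    hill_n = 2,
    max_IGF1 = 400, max_IL6 = 25,
    baseline_IGF1 = 107.8, baseline_IL6 = 3.14,
    slope_IGF1 = -1.95, slope_IL6 = 0.05,
    k_extra = 2.5, mortality_ratio = 2.5,
    extinction = list(horizon = 240, tol = 1e-3),
    grid_n = c(60, 60), separatrix_lines = 25, sweep_n = 400,
    switch_horizons = c(60, 240, 360),
    cohort_horizon = 360,
    figures = FALSE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes, in order: synthetic population + fixture generation, full model
#' calibration, steady-state enumeration, attractor scan, separatrix, switch
#' curves, cohort envelopes and phenotype classification; writes every
#' artefact (CSV/JSON, optional PNG figures) under `out_dir` and a
#' machine-readable `summary.json`. Every output is regenerable from
#' `(config, seed)` alone.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[%5.1fs] %s",
                                         as.numeric(Sys.time() - t0, units = "secs"), msg))

  stage("generate: population and fixtures")
  spec <- population_spec(igf1_mean = config$baseline_IGF1,
                          il6_mean = config$baseline_IL6)
  pop <- generate_population(spec, seed = config$seed)
  strata <- stratify_population(pop)
  trend <- generate_trend_fixture(baseline_IGF1 = config$baseline_IGF1,
                                  baseline_IL6 = config$baseline_IL6,
                                  slope_IGF1 = config$slope_IGF1,
                                  slope_IL6 = config$slope_IL6,
                                  seed = config$seed)
  fixtures <- generate_outcome_fixtures(counts = spec$counts,
                                        mortality_ratio = config$mortality_ratio,
                                        longevity_horizon = config$extinction$horizon,
                                        extinction_tol = config$extinction$tol)
  utils::write.csv(pop, file.path(out_dir, "population.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(strata), file.path(out_dir, "cohorts.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(trend), file.path(out_dir, "trend.csv"),
                   row.names = FALSE)
  for (f in fixtures)
    utils::write.csv(data.frame(time = f$time, survival = f$survival,
                                md_frac0 = f$md_frac0, md_frac36 = f$md_frac36),
                     file.path(out_dir, paste0("outcome_", f$label, ".csv")),
                     row.names = FALSE)
  meta <- list(seed = config$seed, constants = config[c(
    "max_IGF1", "max_IL6", "baseline_IGF1", "baseline_IL6", "slope_IGF1",
    "slope_IL6", "k_extra", "mortality_ratio", "extinction", "hill_n")],
    cutoffs = as.list(attr(pop, "cutoffs")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "fixtures_meta.json"))

  stage("calibrate: trend + cohort fits")
  fit <- fit_frailty_model(trend, fixtures, as.data.frame(strata),
                           max_IGF1 = config$max_IGF1, max_IL6 = config$max_IL6,
                           k_extra = config$k_extra,
                           extinction = config$extinction,
                           hill_n = config$hill_n,
                           require_bistable = config$hill_n >= 2,
                           seed = config$seed)
  if (!fit$bistable)
    warning("calibrated biomarker subsystem is not bistable; ",
            "basin analyses skipped")
  write_params_json(fit, file.path(out_dir, "params.json"))
  write_calibration_json(fit, file.path(out_dir, "calibration.json"))

  scan <- sep <- swG <- swI <- NULL
  if (fit$bistable) {
    stage("scan: basin of attraction grid")
    scan <- scan_attractors(initial_grid(n = config$grid_n), fit$biomarker)
    utils::write.csv(as.data.frame(scan), file.path(out_dir, "phase_diagram.csv"),
                     row.names = FALSE)
    stage("separatrix")
    sep <- find_separatrix(fit$biomarker, n_lines = config$separatrix_lines)
    utils::write.csv(as.data.frame(sep), file.path(out_dir, "separatrix.csv"),
                     row.names = FALSE)
    stage("switch curves")
    swG <- mobility_switch_curve("IGF1", fit$biomarker, fit$outcome,
                                 fixed_value = config$baseline_IL6,
                                 horizons = config$switch_horizons,
                                 n = config$sweep_n)
    swI <- mobility_switch_curve("IL6", fit$biomarker, fit$outcome,
                                 fixed_value = config$baseline_IGF1,
                                 horizons = config$switch_horizons,
                                 n = config$sweep_n)
    utils::write.csv(as.data.frame(swG), file.path(out_dir, "switch_igf1.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(swI), file.path(out_dir, "switch_il6.csv"),
                     row.names = FALSE)
  }

  stage("cohorts: envelopes and phenotype calls")
  md0 <- vapply(fixtures, function(f) f$md_frac0, 0)
  envs <- lapply(seq_len(nrow(strata)), function(i)
    simulate_cohort(as.data.frame(strata)[i, ], fit$biomarker, fit$outcome,
                    horizon = config$cohort_horizon, md0 = md0[i],
                    max_IGF1 = config$max_IGF1, max_IL6 = config$max_IL6))
  env_df <- do.call(rbind, lapply(envs, function(e)
    do.call(rbind, lapply(c("best", "mean", "worst"), function(w)
      data.frame(cohort = e$label, member = w, time = e[[w]]$time,
                 M = e[[w]]$M, MD = e[[w]]$MD, D = e[[w]]$D)))))
  utils::write.csv(env_df, file.path(out_dir, "cohort_envelopes.csv"),
                   row.names = FALSE)
  phen <- NULL
  if (fit$bistable && !is.null(sep) && nrow(sep) >= 2L) {
    phen <- classify_phenotype(pop, sep)
    phen <- data.frame(id = pop$id, phen, cohort = pop$cohort)
    utils::write.csv(phen, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
  }

  if (isTRUE(config$figures)) {
    stage("figures")
    if (fit$bistable) {
      grDevices::png(file.path(out_dir, "fig_phase.png"), 900, 700, res = 120)
      plot(scan); plot(sep, add = TRUE); grDevices::dev.off()
      grDevices::png(file.path(out_dir, "fig_switch_igf1.png"), 900, 700, res = 120)
      plot(swG); grDevices::dev.off()
    }
    grDevices::png(file.path(out_dir, "fig_cohorts.png"), 1000, 800, res = 120)
    op <- graphics::par(mfrow = c(2, 2)); on.exit(graphics::par(op), add = TRUE)
    for (e in envs) plot(e)
    grDevices::dev.off()
  }

  stage("summary")
  mean_traj <- simulate_frailty(c(IGF1 = config$baseline_IGF1,
                                  IL6 = config$baseline_IL6, M = 1, MD = 0),
                                fit$biomarker, fit$outcome, times = 0:60)
  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    bistable = fit$bistable,
    n_attractors = if (fit$bistable) length(unique(stats::na.omit(scan$attractor))) else 1L,
    parameters = as.list(stats::coef(fit)),
    steady_states = as.data.frame(unclass(fit$steady_states)),
    pooled_means = list(IGF1 = mean(pop$IGF1), IL6 = mean(pop$IL6)),
    cohort_counts = as.list(stats::setNames(strata$n, strata$cohort)),
    trend_rates_per_year = list(
      IGF1 = (mean_traj$IGF1[61] - mean_traj$IGF1[1]) / 5,
      IL6 = (mean_traj$IL6[61] - mean_traj$IL6[1]) / 5),
    switch_thresholds = if (fit$bistable) list(
      IGF1 = attr(swG, "thresholds"), IL6 = attr(swI, "thresholds")),
    separatrix_points = if (fit$bistable) nrow(sep) else 0L
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null", dataframe = "rows"),
             file.path(out_dir, "summary.json"))
  invisible(list(fit = fit, population = pop, strata = strata, trend = trend,
                 fixtures = fixtures, scan = scan, separatrix = sep,
                 switch_IGF1 = swG, switch_IL6 = swI, envelopes = envs,
                 phenotypes = phen, summary = summary))
}
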