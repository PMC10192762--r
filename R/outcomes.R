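## Cohort-level outcome analyses: stratification, envelopes, phenotype
## classification and death-state decomposition.

#' Stratify a population into the four biomarker cohorts
#'
#' Partitions individuals by the IGF-1 and IL-6 cut-offs into the 2x2 strata
#' (high/low IGF-1 x low/high IL-6). Individuals exactly on a cut-off are
#' assigned to the lower stratum (documented convention).
#'
#' @param individuals data frame with columns `IGF1`, `IL6` (e.g. from
#'   [generate_population()]).
#' @param cutoff_IGF1,cutoff_IL6 stratum cut-offs; default to the `cutoffs`
#'   attribute carried by generated populations.
#' @return An object of class `cohort_table`: data frame with one row per
#'   stratum (`cohort`, `n`, mean/min/max of each biomarker) and the
#'   per-individual assignment as attribute `assignment`.
#' @export
stratify_population <- function(individuals, cutoff_IGF1 = NULL,
                                cutoff_IL6 = NULL) {
  stopifnot(all(c("IGF1", "IL6") %in% names(individuals)))
  cuts <- attr(individuals, "cutoffs")
  if (is.null(cutoff_IGF1)) cutoff_IGF1 <- cuts[["IGF1"]]
  if (is.null(cutoff_IL6)) cutoff_IL6 <- cuts[["IL6"]]
  if (cutoff_IGF1 <= 0 || cutoff_IL6 <= 0) stop("cut-offs must be positive")
  highG <- individuals$IGF1 > cutoff_IGF1   # boundary -> lower stratum
  highI <- individuals$IL6 > cutoff_IL6
  lab <- ifelse(highG,
                ifelse(highI, "highIGF_highIL6", "highIGF_lowIL6"),
                ifelse(highI, "lowIGF_highIL6", "lowIGF_lowIL6"))
  lab <- factor(lab, levels = .COHORT_LEVELS)
  tab <- do.call(rbind, lapply(.COHORT_LEVELS, function(lv) {
    sel <- individuals[lab == lv, , drop = FALSE]
    data.frame(cohort = lv, n = nrow(sel),
               IGF1 = if (nrow(sel)) mean(sel$IGF1) else NA_real_,
               IL6 = if (nrow(sel)) mean(sel$IL6) else NA_real_,
               IGF1_min = if (nrow(sel)) min(sel$IGF1) else NA_real_,
               IGF1_max = if (nrow(sel)) max(sel$IGF1) else NA_real_,
               IL6_min = if (nrow(sel)) min(sel$IL6) else NA_real_,
               IL6_max = if (nrow(sel)) max(sel$IL6) else NA_real_)
  }))
  stopifnot(sum(tab$n) == nrow(individuals))
  structure(tab, class = c("cohort_table", "data.frame"),
            assignment = lab,
            cutoffs = c(IGF1 = cutoff_IGF1, IL6 = cutoff_IL6))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Population stratification (cut-offs: IGF-1",
      signif(attr(x, "cutoffs")[["IGF1"]], 4), "ng/ml, IL-6",
      signif(attr(x, "cutoffs")[["IL6"]], 4), "pg/ml)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate a cohort's best/mean/worst outcome envelope
#'
#' Simulates three representative individuals for a stratum: the favourable
#' corner of the stratum rectangle (highest IGF-1, lowest IL-6), the stratum
#' mean, and the unfavourable corner (lowest IGF-1, highest IL-6); all other
#' members fall between the corners.
#'
#' @param cohort one row of a [stratify_population()] table (or any list with
#'   `IGF1`, `IL6`, `IGF1_min`, `IGF1_max`, `IL6_min`, `IL6_max`).
#' @param bp,op calibrated parameters.
#' @param horizon simulation horizon (months).
#' @param md0 baseline disabled fraction (applied to all three trajectories).
#' @param max_IGF1,max_IL6 physiological box; baselines outside are rejected.
#' @return An object of class `cohort_envelope`: list of trajectories
#'   `best`, `mean`, `worst` plus the cohort label.
#' @export
simulate_cohort <- function(cohort, bp, op, horizon = 360, md0 = 0,
                            max_IGF1 = 400, max_IL6 = 25) {
  corners <- list(
    best = c(IGF1 = cohort$IGF1_max, IL6 = cohort$IL6_min),
    mean = c(IGF1 = cohort$IGF1, IL6 = cohort$IL6),
    worst = c(IGF1 = cohort$IGF1_min, IL6 = cohort$IL6_max)
  )
  for (cc in corners)
    if (cc[["IGF1"]] <= 0 || cc[["IGF1"]] > max_IGF1 ||
        cc[["IL6"]] <= 0 || cc[["IL6"]] > max_IL6)
      stop("cohort baseline outside the physiological box")
  times <- seq(0, horizon, by = 1)
  trajs <- lapply(corners, function(cc)
    simulate_frailty(c(cc, M = 1 - md0, MD = md0), bp, op, times = times))
  structure(c(trajs, list(label = if (!is.null(cohort$cohort)) as.character(cohort$cohort) else NA)),
            class = "cohort_envelope")
}

#' @export
print.cohort_envelope <- function(x, ...) {
  cat(sprintf("Cohort envelope [%s], horizon %g months\n", x$label,
              max(x$mean$time)))
  for (w in c("best", "mean", "worst")) {
    tr <- x[[w]]
    n <- nrow(tr)
    cat(sprintf("  %-5s start (%.4g, %.4g): endpoint M = %.3g, D = %.3g\n",
                w, tr$IGF1[1], tr$IL6[1], tr$M[n], tr$D[n]))
  }
  invisible(x)
}

#' @export
plot.cohort_envelope <- function(x, ...) {
  graphics::plot(x$mean$time, x$mean$M, type = "n", ylim = c(0, 1),
                 xlab = "time (months)", ylab = "mobility prevalence M", ...)
  graphics::polygon(c(x$best$time, rev(x$worst$time)),
                    c(x$best$M, rev(x$worst$M)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::lines(x$best$time, x$best$M, lty = 2)
  graphics::lines(x$worst$time, x$worst$M, lty = 2)
  graphics::lines(x$mean$time, x$mean$M, lwd = 2)
  graphics::title(main = x$label)
  invisible(x)
}

#' Classify baseline biomarker pairs into mobility phenotypes
#'
#' Side-of-separatrix test: baselines with initial IGF-1 above the critical
#' IGF-1 at their IL-6 level are `mobile_resilient`, below it
#' `frail_declining`; points within `tol` of the curve receive the explicit
#' `boundary` label. Optionally corroborates each call by direct integration
#' to an attractor.
#'
#' @param baseline data frame with columns `IGF1`, `IL6` (or a length-2
#'   numeric `c(IGF1, IL6)`).
#' @param sep a [find_separatrix()] result computed for the same parameters.
#' @param bp the [biomarker_params()] (required when `simulate = TRUE`).
#' @param simulate also classify by long-horizon integration and report both.
#' @param tol boundary half-width (ng/ml); by default computed per point as
#'   half the critical-IGF-1 change across the bracketing scan lines (the
#'   linear-interpolation uncertainty of the curve, large where the curve is
#'   steep) plus twice the bisection tolerance.
#' @return Data frame `IGF1`, `IL6`, `phenotype` (factor
#'   `mobile_resilient`/`frail_declining`/`boundary`), `dist_IGF1` (signed
#'   distance to the curve) and, when simulated, `phenotype_sim`.
#' @export
classify_phenotype <- function(baseline, sep, bp = NULL, simulate = FALSE,
                               tol = NULL) {
  if (is.numeric(baseline) && length(baseline) == 2L)
    baseline <- data.frame(IGF1 = baseline[[1]], IL6 = baseline[[2]])
  stopifnot(all(c("IGF1", "IL6") %in% names(baseline)))
  crit <- separatrix_critical_igf1(sep, baseline$IL6)
  if (is.null(tol)) {
    seg <- findInterval(baseline$IL6, sep$IL6, all.inside = TRUE)
    dcrit <- abs(diff(sep$IGF1_crit))
    tol <- dcrit[seg] / 2 + 2 * attr(sep, "tol_abs")
  }
  d <- baseline$IGF1 - crit
  lab <- ifelse(abs(d) <= tol, "boundary",
                ifelse(d > 0, "mobile_resilient", "frail_declining"))
  out <- data.frame(IGF1 = baseline$IGF1, IL6 = baseline$IL6,
                    phenotype = factor(lab, levels = c("mobile_resilient",
                                                       "frail_declining",
                                                       "boundary")),
                    dist_IGF1 = d)
  if (simulate) {
    stopifnot(inherits(bp, "biomarker_params"))
    stable <- .stable_states(bp)
    out$phenotype_sim <- vapply(seq_len(nrow(out)), function(i) {
      k <- .attractor_of(out$IGF1[i], out$IL6[i], bp, stable)$label
      if (is.na(k)) NA_character_
      else if (k == nrow(stable)) "mobile_resilient" else "frail_declining"
    }, "")
  }
  out
}

#' Decompose cumulative deaths by source compartment
#'
#' Integrates the two death inflows, \eqn{k_{mort} e^{k_{longevity} t} M} (from
#' the mobile state) and \eqn{k_{extra} k_{mort} e^{k_{longevity} t} MD} (from
#' the disabled state), alongside the model; their sum reproduces D(t).
#'
#' @param traj a full-system `frailty_trajectory` (its parameters and initial
#'   state travel with it).
#' @return Data frame `time`, `D`, `D_M`, `D_MD`, `frac_M` (share of deaths so
#'   far occurring from the mobile state).
#' @export
death_state_decomposition <- function(traj) {
  stopifnot(inherits(traj, "frailty_trajectory"))
  op <- attr(traj, "op")
  if (is.null(op)) stop("trajectory has no outcome compartments")
  if (isTRUE(attr(traj, "split_death"))) {
    out <- traj
  } else {
    ini <- attr(traj, "initial")
    out <- simulate_frailty(ini[c("IGF1", "IL6", "M", "MD", "D")],
                            attr(traj, "bp"), op, times = traj$time,
                            split_death = TRUE)
  }
  D_tot <- out$D_M + out$D_MD
  data.frame(time = out$time, D = out$D, D_M = out$D_M, D_MD = out$D_MD,
             frac_M = ifelse(D_tot > 0, out$D_M / D_tot, NA_real_))
}
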