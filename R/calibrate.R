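## Calibration of the model against literature-derived fixtures:
##  1. production/degradation ratios pinned to physiological maxima,
##  2. inhibition strengths (+ timescales) fit to the 5-year biomarker trend,
##  3. k_extra fixed from the literature (2.5),
##  4. k_loss/k_gain/k_mort/k_longevity fit to per-cohort survival and
##     disability series, with the 240-month pooled-extinction constraint.

# residual weighting scales: survival fraction, disabled fraction,
# log10 pooled survival at the extinction horizon
.W_SURV <- 0.01
.W_MD <- 0.02
.W_EXT <- 0.05

#' Fit inhibition strengths and timescales to the biomarker trend
#'
#' Least-squares fit of `(kd_IGF1, kd_IL6, ks_IL6, ks_IGF1)` to the mean
#' five-year biomarker time courses, with the production rates constrained to
#' `kp = max * kd` throughout (the physiological-maximum pin is structural,
#' not penalised). Parameters are log-transformed (positivity by
#' construction) and optimised with Levenberg-Marquardt from a deterministic
#' grid of multi-start points whose inhibition strengths are initialised from
#' the slope-consistency conditions at baseline. A candidate optimum is
#' accepted only if the resulting toggle switch is bistable (when
#' `require_bistable`) and honours any basin probes; among accepted starts
#' the lowest sum of squares wins.
#'
#' A near-linear slow trend identifies the inhibition/timescale parameters
#' only up to a sloppy direction along which the unconstrained least-squares
#' valley is monostable. When no free multi-start optimum is acceptable, the
#' fit retries with the interior (unstable) fixed point anchored at candidate
#' locations between the baseline mean and the physiological maxima, fitting
#' the two timescales per anchor — constrained least squares inside the
#' bistable regime. Anchored candidates must also reproduce the fixture's
#' mean slopes within `slope_tol`.
#'
#' @param trend a `trend_fixture` (see [generate_trend_fixture()]), or any
#'   data frame with columns `time`, `IGF1`, `IL6`.
#' @param max_IGF1,max_IL6 physiological maxima pinning `kp/kd`.
#' @param hill_n Hill coefficient (default 2).
#' @param n_starts number of multi-start points (deterministic grid, up to 8).
#' @param require_bistable reject candidate fits whose biomarker subsystem is
#'   not bistable. An error is raised if no start yields a bistable optimum.
#' @param basin_probes optional structural constraints on the fitted basin
#'   geometry: a list with data-frame entries `resilient` and/or `frail`
#'   (columns `IGF1`, `IL6`); a candidate fit is accepted only if every
#'   resilient probe converges to the high-IGF-1 attractor and every frail
#'   probe to the low-IGF-1 attractor. An optional entry
#'   `majority_resilient = list(points = <data frame>, threshold = <frac>)`
#'   requires at least the given fraction of its points to converge to the
#'   resilient attractor. Used to keep the fitted switch consistent with the
#'   qualitative phenotype assignments of the cohort strata (see
#'   [fit_frailty_model()]).
#' @param slope_tol relative tolerance on the fitted mean slopes for anchored
#'   (constrained) candidates.
#' @param seed stored for provenance; the fit itself is deterministic.
#' @return An object of class `inhibition_fit`: `params`
#'   ([biomarker_params()]), `sse`, `residuals`, `fitted`, `bistable`,
#'   `starts` (per-start diagnostics), `seed`.
#' @export
fit_inhibition <- function(trend, max_IGF1 = 400, max_IL6 = 25, hill_n = 2,
                           n_starts = 8, require_bistable = TRUE,
                           basin_probes = NULL, slope_tol = 0.1, seed = NULL) {
  stopifnot(all(c("time", "IGF1", "IL6") %in% names(trend)))
  t <- trend$time
  G0 <- trend$IGF1[1]; I0 <- trend$IL6[1]
  scG <- max(diff(range(trend$IGF1)), 1e-3 * G0)
  scI <- max(diff(range(trend$IL6)), 1e-3 * I0)
  mk_params <- function(theta) {
    kd1 <- exp(theta[1]); kd2 <- exp(theta[2])
    kp <- pin_production_ratios(max_IGF1, max_IL6, kd1, kd2)
    biomarker_params(kp_IGF1 = kp$kp_IGF1, ks_IL6 = exp(theta[3]), kd_IGF1 = kd1,
                     kp_IL6 = kp$kp_IL6, ks_IGF1 = exp(theta[4]), kd_IL6 = kd2,
                     hill_n = hill_n)
  }
  residfun <- function(theta) {
    p <- mk_params(theta)
    tr <- try(simulate_frailty(c(IGF1 = G0, IL6 = I0), p, op = NULL, times = t),
              silent = TRUE)
    if (inherits(tr, "try-error")) return(rep(1e4, 2L * length(t)))
    c((tr$IGF1 - trend$IGF1) / scG, (tr$IL6 - trend$IL6) / scI)
  }
  # observed mean monthly slopes (regression, robust to endpoint noise)
  # anchor the start points and the slope-fidelity contract
  s1 <- stats::cov(t, trend$IGF1) / stats::var(t)
  s2 <- stats::cov(t, trend$IL6) / stats::var(t)
  ks_from_slope <- function(mx, kd, s, x0, inh0) {
    pull <- s / kd + x0                      # required uninhibited target
    if (pull <= 0) return(NA_real_)
    ks <- (mx / pull - 1) / inh0^hill_n
    if (!is.finite(ks) || ks <= 0) 1e-8 else ks
  }
  probes_ok <- function(p, bist) {
    if (is.null(basin_probes)) return(TRUE)
    if (!bist) return(FALSE)
    stable <- .stable_states(p)
    hit <- function(df, want_idx) vapply(seq_len(nrow(df)), function(i)
      identical(.attractor_of(df$IGF1[i], df$IL6[i], p, stable)$label,
                want_idx), TRUE)
    check <- function(df, want_idx) is.null(df) || all(hit(df, want_idx))
    if (!check(basin_probes$resilient, nrow(stable))) return(FALSE)
    if (!check(basin_probes$frail, 1L)) return(FALSE)
    mr <- basin_probes$majority_resilient
    if (!is.null(mr) &&
        mean(hit(mr$points, nrow(stable))) < mr$threshold) return(FALSE)
    TRUE
  }
  fitted_slopes_ok <- function(p) {
    sim <- simulate_frailty(c(IGF1 = G0, IL6 = I0), p, op = NULL,
                            times = range(t))
    n <- length(t)
    ok1 <- abs((sim$IGF1[2] - sim$IGF1[1]) / (t[n] - t[1]) - s1) <=
      slope_tol * max(abs(s1), 1e-12)
    ok2 <- abs((sim$IL6[2] - sim$IL6[1]) / (t[n] - t[1]) - s2) <=
      slope_tol * max(abs(s2), 1e-12)
    ok1 && ok2
  }
  lm_ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)
  grid <- data.frame(kd1 = c(0.006, 0.02, 0.002, 0.05, 0.02, 0.002, 0.05, 0.006),
                     kd2 = c(0.01, 0.002, 0.01, 0.002, 0.01, 0.002, 0.01, 0.002))
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]
  starts <- list(); fits <- list()
  for (i in seq_len(nrow(grid))) {
    kd1 <- grid$kd1[i]; kd2 <- grid$kd2[i]
    ks_il6 <- ks_from_slope(max_IGF1, kd1, s1, G0, I0)
    ks_igf1 <- ks_from_slope(max_IL6, kd2, s2, I0, G0)
    if (is.na(ks_il6) || is.na(ks_igf1)) {
      starts[[i]] <- list(ok = FALSE, reason = "infeasible slope at start")
      next
    }
    th0 <- log(c(kd1, kd2, ks_il6, ks_igf1))
    fit <- try(minpack.lm::nls.lm(par = th0, fn = residfun, control = lm_ctl),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      starts[[i]] <- list(ok = FALSE, reason = "optimizer error")
      next
    }
    p <- mk_params(fit$par)
    bist <- is_bistable(p)
    acc <- (!require_bistable || bist) && probes_ok(p, bist)
    starts[[i]] <- list(ok = TRUE, sse = fit$deviance, bistable = bist,
                        accepted = acc, info = fit$info, start = exp(th0))
    if (acc) fits[[length(fits) + 1L]] <- list(fit = fit, p = p, bistable = bist)
  }
  # Anchored retries: hold the interior fixed point at (fg*G0, fi*I0) via the
  # nullcline relations, fit the two degradation timescales.
  if (length(fits) == 0L && require_bistable) {
    anchors <- expand.grid(fg = seq(1.05, 1.40, by = 0.05),
                           fi = c(0.70, 0.7625, 0.825, 0.8875, 0.95))
    for (i in seq_len(nrow(anchors))) {
      Gs <- anchors$fg[i] * G0; Is <- anchors$fi[i] * I0
      if (Gs >= max_IGF1 || Is >= max_IL6) next
      ks_il6 <- (max_IGF1 / Gs - 1) / Is^hill_n
      ks_igf1 <- (max_IL6 / Is - 1) / Gs^hill_n
      # slope-consistent timescale starts; skip anchors the flow cannot serve
      den1 <- G0 - max_IGF1 / (1 + ks_il6 * I0^hill_n)
      den2 <- max_IL6 / (1 + ks_igf1 * G0^hill_n) - I0
      kd1 <- -s1 / den1; kd2 <- s2 / den2
      if (!is.finite(kd1) || !is.finite(kd2) || kd1 <= 0 || kd2 <= 0) next
      fit <- try(minpack.lm::nls.lm(
        par = log(c(kd1, kd2)),
        fn = function(th) residfun(c(th[1], th[2], log(ks_il6), log(ks_igf1))),
        control = lm_ctl), silent = TRUE)
      if (inherits(fit, "try-error")) next
      full <- c(fit$par, log(ks_il6), log(ks_igf1))
      p <- mk_params(full)
      bist <- is_bistable(p)
      acc <- bist && probes_ok(p, bist) && fitted_slopes_ok(p)
      starts[[length(starts) + 1L]] <- list(ok = TRUE, sse = fit$deviance,
                                            bistable = bist, accepted = acc,
                                            anchor = c(Gs, Is), info = fit$info)
      if (acc) {
        fit$par <- full
        fits[[length(fits) + 1L]] <- list(fit = fit, p = p, bistable = TRUE)
      }
    }
  }
  if (length(fits) == 0L)
    stop("calibration failure: no acceptable ",
         if (require_bistable) "bistable " else "",
         "optimum found across the multi-start points")
  best <- fits[[which.min(vapply(fits, function(f) f$fit$deviance, 0))]]
  p <- best$p
  tr <- simulate_frailty(c(IGF1 = G0, IL6 = I0), p, op = NULL, times = t)
  structure(list(params = p, sse = best$fit$deviance,
                 residuals = data.frame(time = t,
                                        IGF1 = tr$IGF1 - trend$IGF1,
                                        IL6 = tr$IL6 - trend$IL6),
                 fitted = tr, bistable = best$bistable,
                 optim = list(info = best$fit$info, niter = best$fit$niter),
                 starts = starts, seed = seed),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat("Inhibition-strength fit to the biomarker trend\n")
  cat(sprintf("  SSE = %.4g; bistable: %s\n", x$sse, x$bistable))
  print(x$params)
  invisible(x)
}

#' Calibrate the mortality acceleration to a longevity horizon
#'
#' Solves the closed-form single-compartment survival for the
#' `k_longevity` at which survival reaches `extinction_tol` exactly at
#' `horizon` months, given a baseline mortality rate:
#' \eqn{(k_{mort}/k_l)(e^{k_l h} - 1) = -\log(tol/M_0)}.
#'
#' @param k_mort baseline mortality rate (per month).
#' @param horizon longevity horizon (months), default 240.
#' @param extinction_tol survival level defining "maximal survival".
#' @param M0 initial prevalence.
#' @return The calibrated `k_longevity` (per month).
#' @export
calibrate_longevity <- function(k_mort, horizon = 240, extinction_tol = 1e-3,
                                M0 = 1) {
  stopifnot(k_mort > 0, horizon > 0, extinction_tol > 0, extinction_tol < M0)
  L <- log(M0 / extinction_tol)
  g <- function(kl) (k_mort / kl) * expm1(kl * horizon) - L
  if (k_mort * horizon >= L)
    stop(sprintf(paste0("infeasible pair: k_mort = %g already drives survival ",
                        "below %g before %g months with k_longevity = 0"),
                 k_mort, extinction_tol, horizon))
  hi <- 1e-4
  while (g(hi) < 0 && hi < 10) hi <- hi * 2
  if (g(hi) < 0) stop("bracket failure: no k_longevity <= 10 satisfies the horizon")
  stats::uniroot(g, lower = 1e-12, upper = hi, tol = 1e-14)$root
}

#' Fit the outcome rates to per-cohort survival and disability fixtures
#'
#' Joint least squares over all four cohorts on survival residuals (monthly,
#' whole series), 36-month disabled-fraction residuals, and one strongly
#' weighted residual pinning pooled (count-weighted) survival to
#' `extinction$tol` at `extinction$horizon` months. `k_extra` is held fixed.
#' Each cohort is represented by a single trajectory started from its stratum
#' mean biomarker pair with the fixture's baseline disabled fraction.
#' Parameters `(k_loss, k_gain, k_mort, k_longevity)` are log-transformed and
#' optimised with Levenberg-Marquardt from a small deterministic multi-start
#' grid; [calibrate_longevity()] supplies the `k_longevity` start.
#'
#' @param fixtures a `cohort_outcome_fixtures` list (one per stratum).
#' @param bp calibrated [biomarker_params()].
#' @param baselines data frame with columns `cohort`, `IGF1`, `IL6`: the mean
#'   baseline biomarker pair per stratum (see [stratify_population()]).
#' @param k_extra fixed mortality amplifier for the disabled compartment.
#' @param extinction list `(horizon, tol)` for the pooled-survival constraint,
#'   or `NULL` to drop it.
#' @param n_starts multi-start points (up to 3).
#' @param seed stored for provenance; the fit is deterministic.
#' @return An object of class `outcome_fit`: `params` ([outcome_params()]),
#'   `sse`, `residuals` (per-cohort summaries), `fitted`, diagnostics.
#' @export
fit_outcome_rates <- function(fixtures, bp, baselines, k_extra = 2.5,
                              extinction = list(horizon = 240, tol = 1e-3),
                              n_starts = 3, seed = NULL) {
  stopifnot(inherits(bp, "biomarker_params"))
  labs <- vapply(fixtures, function(f) f$label, "")
  if (!all(labs %in% baselines$cohort))
    stop("baselines must cover every fixture cohort")
  w <- vapply(fixtures, function(f) f$n, 0)
  w <- w / sum(w)
  horizon <- max(fixtures[[1]]$time)
  sim_times <- if (is.null(extinction)) fixtures[[1]]$time else
    sort(unique(c(fixtures[[1]]$time,
                  seq(horizon, extinction$horizon, by = 6), extinction$horizon)))
  i36 <- match(36, sim_times)
  cohort_sims <- function(op) {
    lapply(seq_along(fixtures), function(ci) {
      f <- fixtures[[ci]]
      b <- baselines[match(f$label, baselines$cohort), ]
      simulate_frailty(c(IGF1 = b$IGF1, IL6 = b$IL6,
                         M = 1 - f$md_frac0, MD = f$md_frac0),
                       bp, op, times = sim_times)
    })
  }
  residfun <- function(theta) {
    op <- try(outcome_params(k_loss = exp(theta[1]), k_gain = exp(theta[2]),
                             k_mort = exp(theta[3]), k_longevity = exp(theta[4]),
                             k_extra = k_extra), silent = TRUE)
    if (inherits(op, "try-error")) return(rep(1e4, 10L))
    sims <- try(cohort_sims(op), silent = TRUE)
    if (inherits(sims, "try-error"))
      return(rep(1e4, length(fixtures) * (length(fixtures[[1]]$time) + 1L) + 1L))
    res <- unlist(lapply(seq_along(fixtures), function(ci) {
      f <- fixtures[[ci]]
      s <- sims[[ci]]
      surv <- s$M + s$MD
      idx <- match(f$time, sim_times)
      r <- (surv[idx] - f$survival) / .W_SURV
      mdfrac36 <- s$MD[i36] / max(surv[i36], 1e-12)
      c(r, (mdfrac36 - f$md_frac36) / .W_MD)
    }))
    if (!is.null(extinction)) {
      iH <- match(extinction$horizon, sim_times)
      pooled <- sum(w * vapply(sims, function(s) s$M[iH] + s$MD[iH], 0))
      res <- c(res, (log10(max(pooled, 1e-300)) - log10(extinction$tol)) / .W_EXT)
    }
    res
  }
  # deterministic starts anchored in the fixtures
  Sb <- fixtures[[1]]$survival
  H60 <- -log(max(Sb[length(Sb)], 1e-8))
  b0 <- 0.02
  k_mort0 <- b0 * H60 / expm1(b0 * horizon)
  k_long0 <- tryCatch(calibrate_longevity(k_mort0,
                                          horizon = if (is.null(extinction)) 240 else extinction$horizon,
                                          extinction_tol = if (is.null(extinction)) 1e-3 else extinction$tol),
                      error = function(e) 0.02)
  worst <- fixtures[[length(fixtures)]]
  bw <- baselines[match(worst$label, baselines$cohort), ]
  bb <- baselines[match(fixtures[[1]]$label, baselines$cohort), ]
  k_loss0 <- 0.5 / bw$IL6
  k_gain0 <- 0.5 / bb$IGF1
  # box bounds (log scale): only the k_loss/k_gain ratio is identified once
  # the disability kinetics are fast, so the likelihood has a flat ridge along
  # which unbounded fits drift to arbitrarily stiff rates; the upper bounds
  # keep per-month transition rates on the clinical assessment timescale
  lower <- log(c(k_loss0 / 30, k_gain0 / 30, 1e-7, 1e-5))
  upper <- log(c(k_loss0 * 30, k_gain0 * 30, 0.2, 0.2))
  scales <- c(1, 0.2, 5)[seq_len(min(n_starts, 3))]
  fits <- list(); starts <- list()
  for (i in seq_along(scales)) {
    th0 <- log(c(k_loss0 * scales[i], k_gain0 * scales[i], k_mort0, k_long0))
    th0 <- pmin(pmax(th0, lower), upper)
    fit <- try(minpack.lm::nls.lm(par = th0, fn = residfun,
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      starts[[i]] <- list(ok = FALSE)
      next
    }
    starts[[i]] <- list(ok = TRUE, sse = fit$deviance, info = fit$info)
    fits[[length(fits) + 1L]] <- fit
  }
  if (length(fits) == 0L) {
    stop("outcome-rate fit failed to converge from any start")
  }
  best <- fits[[which.min(vapply(fits, function(f) f$deviance, 0))]]
  # profile polish along the weakly identified ridge: the data pin the
  # k_loss/k_gain ratio tightly but their common scale only softly, so LM
  # stalls there. Coordinate descent along the ridge's natural axes — the
  # joint log-scale direction and the log-ratio direction — finishes the job.
  clamp <- function(th) pmin(pmax(th, lower), upper)
  dirs <- list(c(1, 1, 0, 0), c(1, -1, 0, 0))
  for (pass in 1:6) {
    improved <- FALSE
    for (d in dirs) {
      f1 <- function(s) sum(residfun(clamp(best$par + s * d))^2)
      so <- stats::optimize(f1, c(-1, 1), tol = 1e-4)
      if (so$objective < best$deviance * (1 - 1e-10)) {
        best$par <- clamp(best$par + so$minimum * d)
        best$deviance <- so$objective
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  op <- outcome_params(k_loss = exp(best$par[1]), k_gain = exp(best$par[2]),
                       k_mort = exp(best$par[3]), k_longevity = exp(best$par[4]),
                       k_extra = k_extra)
  sims <- cohort_sims(op)
  percohort <- do.call(rbind, lapply(seq_along(fixtures), function(ci) {
    f <- fixtures[[ci]]
    s <- sims[[ci]]
    idx <- match(f$time, sim_times)
    surv <- s$M[idx] + s$MD[idx]
    data.frame(cohort = f$label,
               rmse_survival = sqrt(mean((surv - f$survival)^2)),
               md_frac36_fit = s$MD[i36] / max(s$M[i36] + s$MD[i36], 1e-12),
               md_frac36_fixture = f$md_frac36)
  }))
  structure(list(params = op, sse = best$deviance, residuals = percohort,
                 fitted = stats::setNames(sims, labs),
                 optim = list(info = best$info, niter = best$niter),
                 starts = starts, seed = seed),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Outcome-rate fit to cohort survival/disability fixtures\n")
  cat(sprintf("  SSE = %.4g\n", x$sse))
  print(x$params)
  print(x$residuals, row.names = FALSE)
  invisible(x)
}

#' Fit the full frailty model to trend and cohort fixtures
#'
#' End-to-end calibration: pins the production/degradation ratios to the
#' physiological maxima, fits the inhibition strengths and timescales to the
#' biomarker trend ([fit_inhibition()]), then fits the outcome rates to the
#' per-cohort survival and disability series with `k_extra` fixed and the
#' longevity horizon enforced ([fit_outcome_rates()]).
#'
#' @param trend a `trend_fixture`.
#' @param cohorts a `cohort_outcome_fixtures` list.
#' @param baselines data frame `cohort`, `IGF1`, `IL6` of stratum mean
#'   baselines.
#' @param max_IGF1,max_IL6 physiological maxima (ng/ml, pg/ml).
#' @param k_extra fixed disabled-compartment mortality amplifier.
#' @param extinction pooled-extinction constraint, list `(horizon, tol)`.
#' @param hill_n Hill coefficient (2 = cooperative default).
#' @param basin_probes `"default"`, `NULL`, or an explicit probe list (see
#'   [fit_inhibition()]). The default anchors the fitted basin geometry to the
#'   qualitative stratum phenotypes: the favourable stratum's expected mean
#'   baseline must lie in the resilient basin, the population mean baseline
#'   (the trend fixture's start) in the frail basin, and the switch along
#'   initial IGF-1 at the mean IL-6 level must occur inside the physiological
#'   scan range. Disabled automatically when `require_bistable = FALSE`.
#' @param seed stored for provenance; the calibration is deterministic.
#' @param ... further arguments passed to [fit_inhibition()].
#' @return An object of class `frailty_fit` (inherits `frailty_model`), with
#'   components `biomarker`, `outcome`, `steady_states`, `bistable`,
#'   `inhibition_fit`, `outcome_fit`, `constants`, `call`. Supports `coef()`,
#'   `summary()`, `predict()`, `simulate()`, `residuals()` and `plot()`.
#' @export
fit_frailty_model <- function(trend, cohorts, baselines,
                              max_IGF1 = 400, max_IL6 = 25, k_extra = 2.5,
                              extinction = list(horizon = 240, tol = 1e-3),
                              hill_n = 2, basin_probes = "default",
                              seed = NULL, ...) {
  if (identical(basin_probes, "default")) {
    basin_probes <- if (isFALSE(list(...)$require_bistable)) NULL else {
      # quantile lattice of the favourable stratum: its majority must be
      # resilient; the switch must occur inside the published scan range at
      # the mean IL-6 level; the declining population mean is frail
      spec <- population_spec()
      qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
      lat <- expand.grid(
        IGF1 = .tnorm_q(qs, spec$igf1$mu, spec$igf1$sd,
                        spec$cutoff_IGF1, spec$igf1$range[2]),
        IL6 = .tlnorm_q(qs, spec$il6$meanlog, spec$il6$sdlog,
                        spec$il6$range[1], spec$cutoff_IL6))
      list(resilient = data.frame(IGF1 = 300, IL6 = trend$IL6[1]),
           frail = data.frame(IGF1 = trend$IGF1[1], IL6 = trend$IL6[1]),
           majority_resilient = list(points = lat, threshold = 0.55))
    }
  }
  inh <- fit_inhibition(trend, max_IGF1 = max_IGF1, max_IL6 = max_IL6,
                        hill_n = hill_n, basin_probes = basin_probes,
                        seed = seed, ...)
  out <- fit_outcome_rates(cohorts, inh$params, baselines, k_extra = k_extra,
                           extinction = extinction, seed = seed)
  ss <- find_steady_states(inh$params)
  structure(list(biomarker = inh$params, outcome = out$params,
                 steady_states = ss,
                 bistable = sum(ss$stability == "stable") == 2L,
                 inhibition_fit = inh, outcome_fit = out,
                 constants = list(max_IGF1 = max_IGF1, max_IL6 = max_IL6,
                                  k_extra = k_extra, extinction = extinction,
                                  hill_n = hill_n),
                 seed = seed, call = match.call()),
            class = c("frailty_fit", "frailty_model"))
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat("Calibrated bistable frailty model\n")
  cat(sprintf("  bistable: %s\n\n", x$bistable))
  print(x$biomarker); cat("\n")
  print(x$outcome); cat("\n")
  print(x$steady_states)
  invisible(x)
}

#' @export
summary.frailty_fit <- function(object, ...) {
  structure(list(coef = stats::coef(object),
                 steady_states = object$steady_states,
                 bistable = object$bistable,
                 trend_sse = object$inhibition_fit$sse,
                 outcome_sse = object$outcome_fit$sse,
                 outcome_residuals = object$outcome_fit$residuals),
            class = "summary.frailty_fit")
}

#' @export
print.summary.frailty_fit <- function(x, ...) {
  cat("Calibrated bistable frailty model\n\nCoefficients:\n")
  print(signif(x$coef, 6))
  cat(sprintf("\nBistable: %s\n", x$bistable))
  print(x$steady_states)
  cat(sprintf("\nTrend-fit SSE: %.4g; outcome-fit SSE: %.4g\n",
              x$trend_sse, x$outcome_sse))
  cat("\nPer-cohort outcome residuals:\n")
  print(x$outcome_residuals, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.frailty_fit <- function(object, which = c("trend", "outcomes"), ...) {
  which <- match.arg(which)
  if (which == "trend") object$inhibition_fit$residuals
  else object$outcome_fit$residuals
}

#' Predict prevalence trajectories for new baselines
#'
#' Simulates the fitted model from each row of `newdata` and returns the
#' requested state variables on the given time grid.
#'
#' @param object a fitted `frailty_fit`.
#' @param newdata data frame with columns `IGF1`, `IL6` and optionally `M`,
#'   `MD` (default: everyone starts mobile).
#' @param times output time grid (months).
#' @param ... unused.
#' @return Long data frame: `id`, `time`, `IGF1`, `IL6`, `M`, `MD`, `D`.
#' @export
predict.frailty_fit <- function(object, newdata, times = 0:240, ...) {
  stopifnot(all(c("IGF1", "IL6") %in% names(newdata)))
  out <- lapply(seq_len(nrow(newdata)), function(i) {
    ini <- c(IGF1 = newdata$IGF1[i], IL6 = newdata$IL6[i],
             M = if ("M" %in% names(newdata)) newdata$M[i] else 1,
             MD = if ("MD" %in% names(newdata)) newdata$MD[i] else 0)
    tr <- simulate_frailty(ini, object$biomarker, object$outcome, times = times)
    data.frame(id = i, as.data.frame(tr))
  })
  do.call(rbind, out)
}

#' Phase-plane plot of a frailty model
#'
#' Draws the two nullclines, the fixed points and (optionally) a few
#' trajectories in the (IGF-1, IL-6) plane.
#'
#' @param x a `frailty_model` or `frailty_fit`.
#' @param igf1_range,il6_range plotting ranges.
#' @param trajectories optional data frame of initial conditions
#'   (`IGF1`, `IL6`) to overlay as integrated paths.
#' @param ... passed to [graphics::plot()].
#' @export
plot.frailty_model <- function(x, igf1_range = NULL, il6_range = NULL,
                               trajectories = NULL, ...) {
  p <- x$biomarker
  if (is.null(igf1_range)) igf1_range <- c(0, 1.05 * p$kp_IGF1 / p$kd_IGF1)
  if (is.null(il6_range)) il6_range <- c(0, 1.05 * p$kp_IL6 / p$kd_IL6)
  G <- seq(igf1_range[1], igf1_range[2], length.out = 300)
  I <- seq(il6_range[1], il6_range[2], length.out = 300)
  graphics::plot(NA, xlim = igf1_range, ylim = il6_range,
                 xlab = "IGF-1 (ng/ml)", ylab = "IL-6 (pg/ml)", ...)
  graphics::lines(.null_G(I, p), I, col = "steelblue")
  graphics::lines(G, .null_I(G, p), col = "firebrick")
  ss <- find_steady_states(p)
  graphics::points(ss$IGF1, ss$IL6, pch = ifelse(ss$stability == "stable", 19, 1),
                   cex = 1.4)
  if (!is.null(trajectories)) {
    for (i in seq_len(nrow(trajectories))) {
      tr <- simulate_frailty(c(IGF1 = trajectories$IGF1[i],
                               IL6 = trajectories$IL6[i]), p,
                             times = .logtimes(1e4))
      graphics::lines(tr$IGF1, tr$IL6, col = grDevices::grey(0.5))
    }
  }
  invisible(x)
}

#' Serialize a calibration result to JSON
#'
#' Writes the fitted parameters, residual summaries, bistability flag and
#' optimiser diagnostics (including the stored seed) as a JSON document.
#'
#' @param fit a `frailty_fit`.
#' @param path file path, or `NULL` to return the JSON string.
#' @return JSON string, invisibly when written.
#' @export
write_calibration_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "frailty_fit"))
  doc <- list(
    parameters = as.list(stats::coef(fit)),
    bistable = fit$bistable,
    steady_states = as.data.frame(unclass(fit$steady_states)),
    trend_fit = list(sse = fit$inhibition_fit$sse,
                     rmse_IGF1 = sqrt(mean(fit$inhibition_fit$residuals$IGF1^2)),
                     rmse_IL6 = sqrt(mean(fit$inhibition_fit$residuals$IL6^2)),
                     optim = fit$inhibition_fit$optim),
    outcome_fit = list(sse = fit$outcome_fit$sse,
                       per_cohort = fit$outcome_fit$residuals,
                       optim = fit$outcome_fit$optim),
    constants = fit$constants,
    seed = fit$seed
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
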