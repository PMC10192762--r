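test_that("longevity calibration solves its defining equation and is monotone", {
  kl <- calibrate_longevity(0.0015, horizon = 240, extinction_tol = 1e-3)
  expect_equal(closed_form_survival(240, 0.0015, kl), 1e-3, tolerance = 1e-7)
  # independent bisection oracle on the defining equation, over a k_mort grid
  oracle_kl <- function(km) {
    g <- function(kl) (km / kl) * expm1(kl * 240) - log(1e3)
    lo <- 1e-10; hi <- 1
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  kms <- c(5e-4, 1e-3, 2e-3, 5e-3, 1e-2)
  kls <- vapply(kms, calibrate_longevity, 0)
  expect_equal(kls, vapply(kms, oracle_kl, 0), tolerance = 1e-8)
  # larger baseline mortality needs less acceleration to hit the same horizon
  expect_true(all(diff(kls) < 0))
  # infeasible pair: baseline mortality alone overshoots the horizon
  expect_error(calibrate_longevity(0.05, horizon = 240, extinction_tol = 1e-3),
               "infeasible")
})

test_that("noise-free trend fit recovers the generating parameters", {
  truth <- cached_fit()$biomarker
  fi <- fit_inhibition(model_trend(truth))
  tru <- coef(frailty_model(truth))
  est <- coef(frailty_model(fi$params))
  expect_lt(max(abs(est - tru) / tru), 0.05)
  expect_lt(max(abs(est[c("ks_IL6", "ks_IGF1")] - tru[c("ks_IL6", "ks_IGF1")]) /
                  tru[c("ks_IL6", "ks_IGF1")]), 0.01)
  expect_true(fi$bistable)
})

test_that("trend fit is deterministic and preserves the pinned ratios exactly", {
  trend <- generate_trend_fixture()
  f1 <- fit_inhibition(trend, seed = 3L)
  f2 <- fit_inhibition(trend, seed = 3L)
  expect_identical(coef(frailty_model(f1$params)), coef(frailty_model(f2$params)))
  expect_equal(f1$params$kp_IGF1 / f1$params$kd_IGF1, 400, tolerance = 1e-12)
  expect_equal(f1$params$kp_IL6 / f1$params$kd_IL6, 25, tolerance = 1e-12)
})

test_that("literature-trend calibration reproduces the annual rates within 10%", {
  fit <- cached_fit()
  sim <- simulate_frailty(c(IGF1 = 107.8, IL6 = 3.14), fit$biomarker,
                          times = 0:60)
  slope_G <- (sim$IGF1[61] - sim$IGF1[1]) / 5
  slope_I <- (sim$IL6[61] - sim$IL6[1]) / 5
  expect_lt(abs(slope_G - (-1.95)) / 1.95, 0.10)
  expect_lt(abs(slope_I - 0.05) / 0.05, 0.10)
  # the calibrated subsystem must be bistable with the flag in sync
  expect_true(fit$bistable)
  expect_equal(sum(fit$steady_states$stability == "stable"), 2L)
})

test_that("noisy trend fits recover the identifiable functionals", {
  # raw (kd, ks) are ridge-degenerate under noise; what the data identify is
  # the underlying mean time course and its two slopes
  truth <- cached_fit()$biomarker
  clean <- model_trend(truth)
  n_ok <- 0L
  for (s in 1:20) {
    noisy <- model_trend(truth, noise = 0.05, seed = 100 + s)
    fi <- try(suppressWarnings(fit_inhibition(noisy, n_starts = 4,
                                              slope_tol = 0.5)), silent = TRUE)
    if (inherits(fi, "try-error")) next
    sim <- simulate_frailty(c(IGF1 = noisy$IGF1[1], IL6 = noisy$IL6[1]),
                            fi$params, times = 0:60)
    rmse_G <- sqrt(mean((sim$IGF1 - clean$IGF1)^2))
    rmse_I <- sqrt(mean((sim$IL6 - clean$IL6)^2))
    # fitted curve must sit within the noise scale of the true curve
    ok_curve <- rmse_G < 2 * 0.05 * 107.8 && rmse_I < 2 * 0.05 * 3.14
    # fitted slopes within 5 slope-standard-errors of the truth (the fitted
    # endpoint slope carries both sampling noise and smoothing bias)
    se_G <- 0.05 * 107.8 / (stats::sd(0:60) * sqrt(61))
    se_I <- 0.05 * 3.14 / (stats::sd(0:60) * sqrt(61))
    sl_G <- (sim$IGF1[61] - sim$IGF1[1]) / 60
    sl_I <- (sim$IL6[61] - sim$IL6[1]) / 60
    ok_slope <- abs(sl_G - (-1.95 / 12)) < 5 * se_G &&
      abs(sl_I - 0.05 / 12) < 5 * se_I
    if (ok_curve && ok_slope) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 15L)
})

test_that("noise-free outcome-rate fit recovers the generating parameters", {
  # designed truth with transition kinetics on the identifiable (clinical)
  # timescale; very fast kinetics leave only the k_loss/k_gain ratio
  # identifiable (M/MD equilibrates within one assessment interval)
  rec <- cached_outcome_recovery()
  tru <- unlist(unclass(rec$truth))[1:4]
  est <- unlist(unclass(rec$fit$params))[1:4]
  expect_lt(max(abs(est - tru) / tru), 0.05)
  # convergence diagnostics travel with the result
  expect_true(is.numeric(rec$fit$sse) && rec$fit$sse >= 0)
  expect_equal(nrow(rec$fit$residuals), 4L)
})

test_that("the fitted hazard of the disabled compartment is k_extra-fold the mobile one", {
  fit <- cached_fit()
  bp <- fit$biomarker; op <- fit$outcome
  expect_equal(op$k_extra, 2.5)
  for (t in c(0, 36, 120)) {
    h_M <- outcome_rhs(c(IGF1 = 100, IL6 = 3, M = 1, MD = 0), bp, op, t = t)[["dD"]]
    h_MD <- outcome_rhs(c(IGF1 = 100, IL6 = 3, M = 0, MD = 1), bp, op, t = t)[["dD"]]
    expect_equal(h_MD / h_M, 2.5)
  }
})

test_that("full calibration closes the loop on its own fixtures", {
  # re-simulated series from the fitted model stay within fitting tolerance
  fit <- cached_fit()
  expect_true(all(fit$outcome_fit$residuals$rmse_survival < 0.05))
  expect_lt(sqrt(mean(fit$inhibition_fit$residuals$IGF1^2)), 1)    # ng/ml
  expect_lt(sqrt(mean(fit$inhibition_fit$residuals$IL6^2)), 0.05)  # pg/ml
  # serialization carries parameters, residuals and the bistability flag
  js <- jsonlite::fromJSON(write_calibration_json(fit))
  expect_true(js$bistable)
  expect_equal(js$parameters$k_extra, 2.5)
  expect_equal(nrow(js$outcome_fit$per_cohort), 4L)
})

test_that("calibration failure is explicit when no bistable optimum exists", {
  # a rising-IGF-1 'trend' cannot be served by the anchored retries
  bad <- data.frame(time = 0:60, IGF1 = 107.8 + 2 * (0:60), IL6 = 3.14 + 0.004 * (0:60))
  expect_error(fit_inhibition(bad, n_starts = 2), "calibration failure")
})
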