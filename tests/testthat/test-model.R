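test_that("biomarker RHS follows the Hill-inhibition kinetic law", {
  p <- biomarker_params(2, 5, 0.4, 1.5, 3, 0.2)
  # zero inhibitor: the inhibition term vanishes
  r <- biomarker_rhs(c(IGF1 = 3, IL6 = 0), p)
  expect_equal(r[["dIGF1"]], 2 - 0.4 * 3)
  # at the uninhibited fixed point kp/kd with IL-6 production suppressed
  p2 <- biomarker_params(2, 5, 0.4, 1.5, 1e8, 0.2)
  r2 <- biomarker_rhs(c(IGF1 = 2 / 0.4, IL6 = 0), p2)
  expect_equal(r2[["dIGF1"]], 0)
  expect_lt(abs(r2[["dIL6"]]), 1e-6)
  # general point against the hand-written law
  r3 <- biomarker_rhs(c(IGF1 = 10, IL6 = 2), p)
  expect_equal(r3[["dIGF1"]], 2 / (1 + 5 * 4) - 0.4 * 10)
  expect_equal(r3[["dIL6"]], 1.5 / (1 + 3 * 100) - 0.2 * 2)
  expect_error(biomarker_rhs(c(IGF1 = -1, IL6 = 0), p), "non-negative")
})

test_that("symmetric toggle vanishes at the scalar-oracle interior root", {
  # oracle: bisection on x (1 + 10 x^2) = 1, i.e. 10 x^3 + x - 1 = 0
  f <- function(x) 10 * x^3 + x - 1
  lo <- 0; hi <- 1
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  expect_equal(x, 0.3930027, tolerance = 1e-6)
  r <- biomarker_rhs(c(IGF1 = x, IL6 = x), sym_toggle())
  expect_lt(max(abs(r)), 1e-10)
})

test_that("outcome RHS conserves total prevalence identically", {
  bp <- biomarker_params(5.2, 0.31, 0.013, 0.19, 5e-4, 0.0074)
  op <- outcome_params(0.2, 0.017, 0.00105, 0.019)
  set.seed(11)
  for (i in 1:25) {
    m <- stats::runif(1)
    st <- c(IGF1 = stats::runif(1, 0, 400), IL6 = stats::runif(1, 0, 25),
            M = m, MD = stats::runif(1, 0, 1 - m), t = stats::runif(1, 0, 240))
    d <- outcome_rhs(st, bp, op)
    expect_equal(sum(d), 0)
    expect_gte(d[["dD"]], 0)
  }
  # frozen dynamics
  op0 <- outcome_params(0, 0, 0, 0.02)
  d0 <- outcome_rhs(c(IGF1 = 100, IL6 = 5, M = 0.6, MD = 0.3, t = 10), bp, op0)
  expect_equal(unname(d0), c(0, 0, 0))
  # single-compartment mortality
  d1 <- outcome_rhs(c(IGF1 = 100, IL6 = 5, M = 1, MD = 0, t = 12), bp,
                    outcome_params(0, 0.01, 0.002, 0.02))
  expect_equal(d1[["dD"]], 0.002 * exp(0.02 * 12))
})

test_that("simulated mobility matches the Gompertz closed form with disability frozen", {
  bp <- biomarker_params(5.2, 0.31, 0.013, 0.19, 5e-4, 0.0074)
  op <- outcome_params(0, 0, 0.002, 0.02)
  tr <- simulate_frailty(c(IGF1 = 100, IL6 = 3, M = 1, MD = 0), bp, op,
                         times = seq(0, 240, 4), rtol = 1e-10, atol = 1e-14)
  expect_equal(tr$M, closed_form_survival(tr$time, 0.002, 0.02),
               tolerance = 1e-6)
})

test_that("closed-form survival behaves at its boundaries", {
  expect_equal(closed_form_survival(0, 0.002, 0.02, M0 = 0.7), 0.7)
  # analytic k_longevity -> 0 limit is exponential decay
  t <- seq(0, 240, 20)
  expect_equal(closed_form_survival(t, 0.003, 1e-12),
               0.7 / 0.7 * exp(-0.003 * t), tolerance = 1e-9)
  expect_equal(closed_form_survival(t, 0.003, 0), exp(-0.003 * t))
})

test_that("trajectories conserve prevalence, keep death monotone and stay bounded", {
  fit <- cached_fit()
  tr <- simulate_frailty(c(IGF1 = 107.8, IL6 = 3.14, M = 1, MD = 0),
                         fit$biomarker, fit$outcome, times = 0:240)
  expect_lt(max(abs(tr$M + tr$MD + tr$D - 1)), 1e-6)
  expect_true(all(diff(tr$D) >= -1e-9))
  expect_silent(validate_trajectory(tr))
  # boundedness of the biomarker subsystem inside the uninhibited box
  set.seed(4)
  for (i in 1:8) {
    p <- random_biomarker_params()
    box <- c(p$kp_IGF1 / p$kd_IGF1, p$kp_IL6 / p$kd_IL6)
    ini <- c(IGF1 = stats::runif(1, 0, box[1]), IL6 = stats::runif(1, 0, box[2]))
    s <- simulate_frailty(ini, p, times = c(0, 10^seq(0, 4, 0.5)))
    expect_true(all(s$IGF1 >= -1e-9 & s$IGF1 <= box[1] * (1 + 1e-6)))
    expect_true(all(s$IL6 >= -1e-9 & s$IL6 <= box[2] * (1 + 1e-6)))
  }
})

test_that("frozen outcome rates leave the prevalence scores constant", {
  bp <- biomarker_params(5.2, 0.31, 0.013, 0.19, 5e-4, 0.0074)
  op0 <- outcome_params(0, 0, 0, 0.02)
  tr <- simulate_frailty(c(IGF1 = 107.8, IL6 = 3.14, M = 0.8, MD = 0.15),
                         bp, op0, times = 0:240)
  expect_equal(tr$M, rep(0.8, 241), tolerance = 1e-8)
  expect_equal(tr$MD, rep(0.15, 241), tolerance = 1e-8)
  expect_equal(tr$D, rep(0.05, 241), tolerance = 1e-7)
})

test_that("simulate guards its inputs and validates invariants", {
  bp <- biomarker_params(1, 10, 1, 1, 10, 1)
  expect_error(simulate_frailty(c(IGF1 = -1, IL6 = 1), bp), "non-negative")
  expect_error(simulate_frailty(c(IGF1 = 1, IL6 = 1), bp, times = c(0, 0, 1)),
               "strictly increasing")
  op <- outcome_params(0.1, 0.01, 0.001, 0.02)
  expect_error(simulate_frailty(c(IGF1 = 1, IL6 = 1, M = 0.9, MD = 0.3), bp, op),
               "sum to 1")
  tr <- simulate_frailty(c(IGF1 = 1, IL6 = 0.2), bp, times = 0:10)
  bad <- tr
  bad$IGF1[3] <- -0.5
  expect_error(validate_trajectory(bad), "negative")
})

test_that("simulate method on a model object returns the same trajectory", {
  fit <- cached_fit()
  t1 <- simulate(fit, initial = c(IGF1 = 120, IL6 = 2, M = 1, MD = 0),
                 times = 0:24)
  t2 <- simulate_frailty(c(IGF1 = 120, IL6 = 2, M = 1, MD = 0),
                         fit$biomarker, fit$outcome, times = 0:24)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})
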