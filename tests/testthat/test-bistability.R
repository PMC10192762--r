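test_that("attractor scan finds exactly two basins for the calibrated model", {
  fit <- cached_fit()
  sc <- scan_attractors(initial_grid(n = c(12, 12)), fit$biomarker)
  labs <- unique(stats::na.omit(sc$attractor))
  expect_setequal(labs, 1:2)
  expect_length(attr(sc, "unassigned"), 0L)
  expect_true(all(is.finite(sc$t_converge)))
})

test_that("monostable parameters label every node identically", {
  p0 <- biomarker_params(2, 0, 0.05, 3, 0, 0.05)
  sc <- scan_attractors(initial_grid(igf1_range = c(1, 60),
                                     il6_range = c(1, 50), n = c(6, 6)), p0)
  expect_equal(unique(sc$attractor), 1L)
})

test_that("labels along a fixed IL-6 row change at most once (fine-sweep oracle)", {
  fit <- cached_fit()
  bp <- fit$biomarker
  stable <- bifrail:::.stable_states(bp)
  row_labels <- function(n, il6) vapply(seq(40, 300, length.out = n), function(g)
    bifrail:::.attractor_of(g, il6, bp, stable)$label, 0L)
  coarse <- row_labels(15, 2.5)
  fine <- row_labels(150, 2.5)
  expect_lte(sum(diff(coarse) != 0), 1L)
  expect_lte(sum(diff(fine) != 0), 1L)
  # transition positions agree within one coarse cell
  if (any(diff(coarse) != 0) && any(diff(fine) != 0)) {
    gc <- seq(40, 300, length.out = 15)[which(diff(coarse) != 0)]
    gf <- seq(40, 300, length.out = 150)[which(diff(fine) != 0)]
    expect_lt(abs(gc - gf), diff(seq(40, 300, length.out = 15))[1])
  }
})

test_that("symmetric toggle's separatrix is the diagonal", {
  p <- sym_toggle()
  sep <- find_separatrix(p, igf1_range = c(0.05, 0.95),
                         il6_range = c(0.15, 0.85), n_lines = 8, tol = 0.001)
  expect_gte(nrow(sep), 6L)
  expect_lt(max(abs(sep$IGF1_crit - sep$IL6)), 3 * attr(sep, "tol_abs"))
})

test_that("separatrix points split attractors and track the grid scan", {
  fit <- cached_fit()
  bp <- fit$biomarker
  sep <- cached_separatrix()
  stable <- bifrail:::.stable_states(bp)
  tol_abs <- attr(sep, "tol_abs")
  for (i in seq_len(nrow(sep))) {
    lo <- bifrail:::.attractor_of(sep$IGF1_crit[i] - 2 * tol_abs, sep$IL6[i],
                                  bp, stable)$label
    hi <- bifrail:::.attractor_of(sep$IGF1_crit[i] + 2 * tol_abs, sep$IL6[i],
                                  bp, stable)$label
    expect_false(identical(lo, hi))
  }
  # critical IGF-1 grows with IL-6
  expect_true(all(diff(sep$IGF1_crit) > 0))
  # consistency with an independent coarse scan: the labelled transition cell
  # brackets the interpolated separatrix
  sc <- scan_attractors(initial_grid(n = c(10, 10)), bp)
  g <- attr(sc, "grid")
  cell <- diff(g$IGF1)[1]
  for (j in seq_along(g$IL6)) {
    row <- sc[sc$IL6_0 == g$IL6[j], ]
    tr <- which(diff(row$attractor) != 0)
    if (length(tr) == 1L &&
        g$IL6[j] >= min(sep$IL6) && g$IL6[j] <= max(sep$IL6)) {
      crit <- separatrix_critical_igf1(sep, g$IL6[j])
      expect_lt(abs((row$IGF1_0[tr] + row$IGF1_0[tr + 1]) / 2 - crit), cell)
    }
  }
})

test_that("bistability requires the cooperative Hill exponent", {
  fit <- cached_fit()
  b <- fit$biomarker
  p1 <- biomarker_params(b$kp_IGF1, b$ks_IL6, b$kd_IGF1,
                         b$kp_IL6, b$ks_IGF1, b$kd_IL6, hill_n = 1)
  expect_false(is_bistable(p1))
  sc <- scan_attractors(initial_grid(n = c(6, 6)), p1)
  expect_equal(length(unique(stats::na.omit(sc$attractor))), 1L)
})

test_that("decoupled outcomes give a flat switch curve with no threshold", {
  fit <- cached_fit()
  op0 <- outcome_params(0, 0, fit$outcome$k_mort, fit$outcome$k_longevity)
  sw <- mobility_switch_curve("IGF1", fit$biomarker, op0,
                              horizons = c(60, 240), n = 25)
  for (h in c(60, 240)) {
    m <- sw$M[sw$horizon == h]
    expect_lt(diff(range(m)), 1e-6)   # solver-tolerance scale
  }
  thr <- attr(sw, "thresholds")
  expect_true(all(is.na(thr$critical)))
})

test_that("the mobility switch sharpens with horizon and saturates its basins", {
  fit <- cached_fit()
  sw <- mobility_switch_curve("IGF1", fit$biomarker, fit$outcome, n = 120)
  thr <- attr(sw, "thresholds")
  expect_true(all(diff(thr$steepness) > 0))
  expect_false(is.na(thr$critical[thr$horizon == 360]))
  # near-step at 30 years: the frail floor is a few percent of the mobile top
  m360 <- sw[sw$horizon == 360, ]
  floor_vals <- m360$M_cond[m360$value <= stats::quantile(m360$value, 0.1)]
  expect_lt(mean(floor_vals), 0.05 * max(m360$M_cond))
  # IL-6 sweep shows the mirrored switch
  swI <- mobility_switch_curve("IL6", fit$biomarker, fit$outcome, n = 100)
  thrI <- attr(swI, "thresholds")
  expect_true(all(diff(thrI$steepness) > 0))
})

test_that("threshold detection is stable under sweep refinement", {
  fit <- cached_fit()
  c1 <- critical_threshold(
    mobility_switch_curve("IGF1", fit$biomarker, fit$outcome,
                          horizons = 360, n = 80), 360)
  c2 <- critical_threshold(
    mobility_switch_curve("IGF1", fit$biomarker, fit$outcome,
                          horizons = 360, n = 160), 360)
  expect_lt(abs(c1 - c2), (300 - 40) / 79)
})

test_that("mortality-free long-horizon threshold converges to the separatrix", {
  fit <- cached_fit()
  op0 <- outcome_params(fit$outcome$k_loss, fit$outcome$k_gain, 1e-9, 1e-9)
  sw <- mobility_switch_curve("IGF1", fit$biomarker, op0,
                              horizons = 1200, n = 150)
  crit <- critical_threshold(sw, 1200)
  sep_crit <- separatrix_critical_igf1(cached_separatrix(), 3.14)
  expect_lt(abs(crit - sep_crit), (300 - 40) / 149)
})

test_that("critical_threshold flags absent transitions and unknown horizons", {
  fit <- cached_fit()
  p0 <- biomarker_params(400 * 0.02, 0, 0.02, 25 * 0.01, 0, 0.01)
  sw <- mobility_switch_curve("IGF1", p0, fit$outcome, horizons = 240, n = 30)
  expect_true(is.na(critical_threshold(sw, 240)))
  expect_error(critical_threshold(sw, 999), "not present")
})
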