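test_that("stratification reproduces the designed counts exactly", {
  st <- cached_strata()
  expect_equal(st$n, c(398L, 128L, 142L, 50L))
  expect_equal(sum(st$n), 718L)
  expect_equal(as.character(st$cohort),
               c("highIGF_lowIL6", "highIGF_highIL6",
                 "lowIGF_lowIL6", "lowIGF_highIL6"))
})

test_that("stratification is exhaustive, order-invariant and boundary-consistent", {
  pop <- cached_population()
  cuts <- attr(pop, "cutoffs")
  shuffled <- pop[sample(nrow(pop)), ]
  st2 <- stratify_population(shuffled, cuts[["IGF1"]], cuts[["IL6"]])
  expect_equal(st2$n, cached_strata()$n)
  # cut-offs beyond the data range put everyone in one stratum
  st3 <- stratify_population(pop, cutoff_IGF1 = 1000, cutoff_IL6 = 0.01)
  expect_equal(st3$n[st3$cohort == "lowIGF_highIL6"], 718L)
  # a value exactly on the cut-off goes to the lower stratum
  df <- data.frame(IGF1 = c(cuts[["IGF1"]], cuts[["IGF1"]] + 1e-6),
                   IL6 = c(cuts[["IL6"]], cuts[["IL6"]] + 1e-6))
  st4 <- stratify_population(df, cuts[["IGF1"]], cuts[["IL6"]])
  a <- attr(st4, "assignment")
  expect_equal(as.character(a[1]), "lowIGF_lowIL6")
  expect_equal(as.character(a[2]), "highIGF_highIL6")
})

test_that("low-IGF-1/high-IL-6 quadrant classifies uniformly frail", {
  pop <- cached_population()
  sep <- cached_separatrix()
  worst <- pop[pop$cohort == "lowIGF_highIL6", ]
  ph <- classify_phenotype(worst[, c("IGF1", "IL6")], sep)
  expect_true(all(ph$phenotype == "frail_declining"))
})

test_that("phenotype calls: steady states, dichotomy and majority structure", {
  fit <- cached_fit()
  sep <- cached_separatrix()
  ss <- fit$steady_states
  stable <- ss[ss$stability == "stable", ]
  ph <- classify_phenotype(stable[, c("IGF1", "IL6")], sep)
  expect_equal(as.character(ph$phenotype),
               c("frail_declining", "mobile_resilient"))
  # every call is one of the two phenotypes or the explicit boundary label
  pop <- cached_population()
  all_ph <- classify_phenotype(pop[, c("IGF1", "IL6")], sep)
  expect_true(all(!is.na(all_ph$phenotype)))
  # favourable stratum majority resilient; declining pooled mean frail
  fav <- all_ph$phenotype[pop$cohort == "highIGF_lowIL6"]
  expect_gt(mean(fav == "mobile_resilient"), 0.5)
  mean_ph <- classify_phenotype(c(107.8, 3.14), sep)
  expect_equal(as.character(mean_ph$phenotype), "frail_declining")
})

test_that("separatrix-side labels agree with direct simulation", {
  fit <- cached_fit()
  sep <- cached_separatrix()
  set.seed(21)
  base <- data.frame(IGF1 = stats::runif(60, 40, 300),
                     IL6 = stats::runif(60, 1, 10))
  ph <- classify_phenotype(base, sep, bp = fit$biomarker, simulate = TRUE)
  non_boundary <- ph$phenotype != "boundary"
  expect_gt(sum(non_boundary), 50)
  expect_equal(as.character(ph$phenotype[non_boundary]),
               ph$phenotype_sim[non_boundary])
})

test_that("cohort envelopes express the published phenotype assignments", {
  fit <- cached_fit()
  st <- as.data.frame(cached_strata())
  fx <- generate_outcome_fixtures()
  md0 <- vapply(fx, function(f) f$md_frac0, 0)
  envs <- lapply(seq_len(4), function(i)
    simulate_cohort(st[i, ], fit$biomarker, fit$outcome, md0 = md0[i]))
  # worst stratum: every member declines to (near) zero mobility
  worst <- envs[[4]]
  for (w in c("best", "mean", "worst"))
    expect_lt(utils::tail(worst[[w]]$M, 1), 0.01)
  # the mean member of the favourable stratum is resilient
  ph <- classify_phenotype(c(st$IGF1[1], st$IL6[1]), cached_separatrix())
  expect_equal(as.character(ph$phenotype), "mobile_resilient")
  # envelope containment: the mean trajectory stays inside the corner band
  for (e in envs) {
    hi <- pmax(e$best$M, e$worst$M) + 1e-9
    lo <- pmin(e$best$M, e$worst$M) - 1e-9
    expect_true(all(e$mean$M <= hi & e$mean$M >= lo))
  }
  # out-of-range baseline is rejected
  bad <- st[1, ]; bad$IGF1_max <- 500
  expect_error(simulate_cohort(bad, fit$biomarker, fit$outcome),
               "physiological box")
})

test_that("zero outcome rates freeze the cohort envelopes", {
  fit <- cached_fit()
  st <- as.data.frame(cached_strata())
  op0 <- outcome_params(0, 0, 0, 0.02)
  e <- simulate_cohort(st[1, ], fit$biomarker, op0, horizon = 120, md0 = 0.1)
  for (w in c("best", "mean", "worst"))
    expect_equal(e[[w]]$M, rep(0.9, 121), tolerance = 1e-8)
})

test_that("death-state decomposition books every death to a source compartment", {
  fit <- cached_fit()
  st <- as.data.frame(cached_strata())
  tr <- simulate_frailty(c(IGF1 = st$IGF1[2], IL6 = st$IL6[2],
                           M = 0.9, MD = 0.1),
                         fit$biomarker, fit$outcome, times = 0:360)
  dd <- death_state_decomposition(tr)
  expect_lt(max(abs(dd$D - (dd$D_M + dd$D_MD))), 1e-6)
  expect_true(all(diff(dd$D_M) >= -1e-9) && all(diff(dd$D_MD) >= -1e-9))
  # with the disabled compartment never populated, all deaths are mobile
  op_m <- outcome_params(0, 0.01, fit$outcome$k_mort, fit$outcome$k_longevity)
  tr_m <- simulate_frailty(c(IGF1 = 120, IL6 = 2, M = 1, MD = 0),
                           fit$biomarker, op_m, times = 0:240)
  dd_m <- death_state_decomposition(tr_m)
  expect_equal(utils::tail(dd_m$frac_M, 1), 1, tolerance = 1e-8)
  # high-IGF/high-IL6 mean individual: mobile-death share near 30% (loose)
  expect_gt(utils::tail(dd$frac_M, 1), 0.15)
  expect_lt(utils::tail(dd$frac_M, 1), 0.45)
})
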