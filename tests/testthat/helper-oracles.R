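# Shared oracles, generators and a per-session cache of the (expensive)
# calibrated model fit.

sym_toggle <- function(ks = 10) biomarker_params(1, ks, 1, 1, ks, 1)

# Brute-force fixed-point oracle: dense scan of the composed nullcline and
# plain interval-halving bisection, independent of find_steady_states().
oracle_fixed_points <- function(p, n_grid = 2000) {
  f <- function(I) (p$kp_IGF1 / p$kd_IGF1) / (1 + p$ks_IL6 * I^p$hill_n)
  g <- function(G) (p$kp_IL6 / p$kd_IL6) / (1 + p$ks_IGF1 * G^p$hill_n)
  h <- function(G) G - f(g(G))
  Gmax <- p$kp_IGF1 / p$kd_IGF1
  xs <- seq(0, Gmax * (1 + 1e-9), length.out = n_grid)
  hs <- vapply(xs, h, 0)
  roots <- xs[hs == 0]
  for (i in seq_len(n_grid - 1L)) {
    if (hs[i] * hs[i + 1L] < 0) {
      lo <- xs[i]; hi <- xs[i + 1L]; flo <- hs[i]
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        fm <- h(mid)
        if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-7 * max(1, Gmax))]
  data.frame(IGF1 = roots, IL6 = g(roots))
}

random_biomarker_params <- function() {
  biomarker_params(
    kp_IGF1 = exp(stats::runif(1, log(0.1), log(20))),
    ks_IL6 = exp(stats::runif(1, log(1e-3), log(50))),
    kd_IGF1 = exp(stats::runif(1, log(5e-3), log(0.5))),
    kp_IL6 = exp(stats::runif(1, log(0.1), log(20))),
    ks_IGF1 = exp(stats::runif(1, log(1e-3), log(50))),
    kd_IL6 = exp(stats::runif(1, log(5e-3), log(0.5))))
}

random_bistable_params <- function(max_tries = 500) {
  for (i in seq_len(max_tries)) {
    p <- random_biomarker_params()
    if (is_bistable(p)) return(p)
  }
  stop("no bistable parameter set found")
}

.tcache <- new.env(parent = emptyenv())

cached_population <- function() {
  if (is.null(.tcache$pop)) .tcache$pop <- generate_population(seed = 1L)
  .tcache$pop
}

cached_strata <- function() {
  if (is.null(.tcache$st)) .tcache$st <- stratify_population(cached_population())
  .tcache$st
}

cached_fit <- function() {
  if (is.null(.tcache$fit))
    .tcache$fit <- fit_frailty_model(generate_trend_fixture(),
                                     generate_outcome_fixtures(),
                                     as.data.frame(cached_strata()),
                                     seed = 1L)
  .tcache$fit
}

cached_separatrix <- function() {
  if (is.null(.tcache$sep))
    .tcache$sep <- find_separatrix(cached_fit()$biomarker)
  .tcache$sep
}

# noise-free outcome-rate recovery against a designed identifiable truth
cached_outcome_recovery <- function() {
  if (is.null(.tcache$orec)) {
    fit <- cached_fit()
    truth <- outcome_params(k_loss = 0.2, k_gain = 0.02,
                            k_mort = 0.00107, k_longevity = 0.0194)
    bl <- as.data.frame(cached_strata())
    fx <- model_outcome_fixtures(fit$biomarker, truth, bl)
    pooled240 <- pooled_survival(fit$biomarker, truth, bl,
                                 md0 = c(0.05, 0.10, 0.15, 0.30),
                                 counts = c(398, 128, 142, 50),
                                 times = c(0, 240))[2]
    fo <- fit_outcome_rates(fx, fit$biomarker, bl,
                            extinction = list(horizon = 240, tol = pooled240))
    .tcache$orec <- list(truth = truth, fit = fo)
  }
  .tcache$orec
}

# Model-generated fixtures for parameter-recovery studies.
model_trend <- function(bp, noise = 0, seed = 1L,
                        start = c(IGF1 = 107.8, IL6 = 3.14)) {
  sim <- simulate_frailty(start, bp, times = 0:60)
  G <- sim$IGF1; I <- sim$IL6
  if (noise > 0) {
    set.seed(seed)
    G <- G * (1 + stats::rnorm(61, 0, noise))
    I <- I * (1 + stats::rnorm(61, 0, noise))
  }
  data.frame(time = 0:60, IGF1 = G, IL6 = I)
}

model_outcome_fixtures <- function(bp, op, baselines,
                                   counts = c(398L, 128L, 142L, 50L),
                                   md0 = c(0.05, 0.10, 0.15, 0.30),
                                   noise = 0, seed = 1L) {
  out <- lapply(seq_len(nrow(baselines)), function(i) {
    s <- simulate_frailty(c(IGF1 = baselines$IGF1[i], IL6 = baselines$IL6[i],
                            M = 1 - md0[i], MD = md0[i]), bp, op, times = 0:60)
    surv <- s$M + s$MD
    if (noise > 0) {
      set.seed(seed + i)
      surv <- pmin(1, pmax(1e-6, surv * (1 + stats::rnorm(61, 0, noise))))
      surv[1] <- 1
    }
    structure(list(label = as.character(baselines$cohort[i]), n = counts[i],
                   time = 0:60, survival = surv, md_frac0 = md0[i],
                   md_frac36 = s$MD[37] / (s$M[37] + s$MD[37])),
              class = "cohort_outcome_fixture")
  })
  names(out) <- as.character(baselines$cohort)
  out
}

# pooled count-weighted survival of the four cohorts under given parameters
pooled_survival <- function(bp, op, baselines, md0, counts, times) {
  w <- counts / sum(counts)
  surv <- Map(function(i) {
    s <- simulate_frailty(c(IGF1 = baselines$IGF1[i], IL6 = baselines$IL6[i],
                            M = 1 - md0[i], MD = md0[i]), bp, op, times = times)
    s$M + s$MD
  }, seq_len(nrow(baselines)))
  Reduce(`+`, Map(`*`, surv, w))
}
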