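## Synthetic population and calibration-fixture generators. Everything the
## pipeline consumes is generated here from a handful of literature constants:
## baseline means 107.8 ng/ml (IGF-1) and 3.14 pg/ml (IL-6), annual trends
## -1.95 ng/ml and +0.05 pg/ml, four strata with counts 398/128/142/50,
## a 2.5x extreme-cohort five-year mortality ratio, and population extinction
## (to a configurable tolerance) at 240 months.

.COHORT_LEVELS <- c("highIGF_lowIL6", "highIGF_highIL6",
                    "lowIGF_lowIL6", "lowIGF_highIL6")

## --- truncated-distribution helpers (normal for IGF-1, log-normal for IL-6) ---

.tnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd; be <- (b - mu) / sd
  Z <- stats::pnorm(be) - stats::pnorm(al)
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) / Z
}

.tnorm_q <- function(p, mu, sd, a, b) {
  Fa <- stats::pnorm(a, mu, sd); Fb <- stats::pnorm(b, mu, sd)
  stats::qnorm(Fa + p * (Fb - Fa), mu, sd)
}

.tnorm_sample <- function(n, mu, sd, a, b) {
  u <- stats::runif(n)
  .tnorm_q(u, mu, sd, a, b)
}

.tlnorm_mean <- function(ml, sl, a, b) {
  Fa <- stats::plnorm(a, ml, sl); Fb <- stats::plnorm(b, ml, sl)
  num <- stats::pnorm((log(b) - ml - sl^2) / sl) -
    stats::pnorm((log(a) - ml - sl^2) / sl)
  exp(ml + sl^2 / 2) * num / (Fb - Fa)
}

.tlnorm_q <- function(p, ml, sl, a, b) {
  Fa <- stats::plnorm(a, ml, sl); Fb <- stats::plnorm(b, ml, sl)
  stats::qlnorm(Fa + p * (Fb - Fa), ml, sl)
}

.tlnorm_sample <- function(n, ml, sl, a, b) .tlnorm_q(stats::runif(n), ml, sl, a, b)

#' Specification of the synthetic baseline population
#'
#' Defines the joint baseline distribution of (IGF-1, IL-6) in a population of
#' older women stratified into four biomarker cohorts. IGF-1 is truncated
#' normal (clinical range bounds), IL-6 log-normal (right-skewed cytokine)
#' truncated below the model's physiological ceiling. Location parameters are
#' solved so the truncated marginal means equal the configured population
#' means exactly, and the stratum cut-offs are the marginal quantiles implied
#' by the configured counts (IGF-1 low = bottom `(n3+n4)/n`, IL-6 high = top
#' `(n2+n4)/n`), so stratified sampling with exact per-stratum counts is
#' consistent with the marginals (the printed 2x2 counts are very nearly
#' independent).
#'
#' @param n total population size.
#' @param counts named per-stratum counts (must sum to `n`), in the order
#'   high-IGF/low-IL6, high-IGF/high-IL6, low-IGF/low-IL6, low-IGF/high-IL6.
#' @param igf1_mean,igf1_sd,igf1_range IGF-1 truncated-normal parameters
#'   (ng/ml); the underlying normal mean is solved so the truncated mean
#'   equals `igf1_mean`.
#' @param il6_mean,il6_sdlog,il6_range IL-6 truncated log-normal parameters
#'   (pg/ml); the log-mean is solved so the truncated mean equals `il6_mean`.
#' @return An object of class `population_spec` carrying the solved
#'   distribution parameters and the stratum cut-offs (`cutoff_IGF1`,
#'   `cutoff_IL6`).
#' @export
population_spec <- function(n = 718L,
                            counts = c(highIGF_lowIL6 = 398L,
                                       highIGF_highIL6 = 128L,
                                       lowIGF_lowIL6 = 142L,
                                       lowIGF_highIL6 = 50L),
                            igf1_mean = 107.8, igf1_sd = 45,
                            igf1_range = c(15, 315),
                            il6_mean = 3.14, il6_sdlog = 0.6,
                            il6_range = c(0.4, 20)) {
  if (!identical(names(counts), .COHORT_LEVELS))
    stop("'counts' must be named ", paste(.COHORT_LEVELS, collapse = ", "))
  if (sum(counts) != n) stop("per-stratum counts must sum to n")
  if (any(counts <= 0)) stop("counts must be positive")
  mu <- stats::uniroot(function(m)
    .tnorm_mean(m, igf1_sd, igf1_range[1], igf1_range[2]) - igf1_mean,
    interval = igf1_mean + c(-3, 3) * igf1_sd, tol = 1e-12)$root
  ml <- stats::uniroot(function(m)
    .tlnorm_mean(m, il6_sdlog, il6_range[1], il6_range[2]) - il6_mean,
    interval = log(il6_mean) + c(-2, 2), tol = 1e-12)$root
  p_lowG <- (counts[["lowIGF_lowIL6"]] + counts[["lowIGF_highIL6"]]) / n
  p_highI <- (counts[["highIGF_highIL6"]] + counts[["lowIGF_highIL6"]]) / n
  cut_G <- .tnorm_q(p_lowG, mu, igf1_sd, igf1_range[1], igf1_range[2])
  cut_I <- .tlnorm_q(1 - p_highI, ml, il6_sdlog, il6_range[1], il6_range[2])
  structure(list(n = as.integer(n), counts = counts,
                 igf1 = list(mean = igf1_mean, sd = igf1_sd, mu = mu,
                             range = igf1_range),
                 il6 = list(mean = il6_mean, sdlog = il6_sdlog, meanlog = ml,
                            range = il6_range),
                 cutoff_IGF1 = cut_G, cutoff_IL6 = cut_I),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("Synthetic population spec: n = %d\n", x$n))
  cat(sprintf("  IGF-1 ~ truncNorm(mean %.4g, sd %.4g) on [%g, %g] ng/ml\n",
              x$igf1$mean, x$igf1$sd, x$igf1$range[1], x$igf1$range[2]))
  cat(sprintf("  IL-6  ~ truncLogNorm(mean %.4g, sdlog %.4g) on [%g, %g] pg/ml\n",
              x$il6$mean, x$il6$sdlog, x$il6$range[1], x$il6$range[2]))
  cat(sprintf("  cut-offs: IGF-1 %.4g ng/ml, IL-6 %.4g pg/ml; counts %s\n",
              x$cutoff_IGF1, x$cutoff_IL6,
              paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Analytic stratum mean baselines
#'
#' Expected (IGF-1, IL-6) within each stratum rectangle under the spec's
#' truncated marginal distributions — the deterministic counterpart of the
#' empirical stratum means of a generated population (no sampling involved).
#'
#' @param spec a [population_spec()].
#' @return Data frame `cohort`, `IGF1`, `IL6`.
#' @export
stratum_mean_baselines <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  gR <- spec$igf1$range; iR <- spec$il6$range
  cG <- spec$cutoff_IGF1; cI <- spec$cutoff_IL6
  gm <- c(high = .tnorm_mean(spec$igf1$mu, spec$igf1$sd, cG, gR[2]),
          low = .tnorm_mean(spec$igf1$mu, spec$igf1$sd, gR[1], cG))
  im <- c(low = .tlnorm_mean(spec$il6$meanlog, spec$il6$sdlog, iR[1], cI),
          high = .tlnorm_mean(spec$il6$meanlog, spec$il6$sdlog, cI, iR[2]))
  data.frame(cohort = .COHORT_LEVELS,
             IGF1 = gm[c("high", "high", "low", "low")],
             IL6 = im[c("low", "high", "low", "high")],
             row.names = NULL)
}

#' Generate a synthetic baseline population
#'
#' Stratified sampling with exact per-stratum counts: within each stratum
#' rectangle, IGF-1 and IL-6 are drawn independently from the spec's marginal
#' distributions restricted to that rectangle (inverse-CDF sampling), so the
#' configured counts are reproduced exactly and the pooled marginal means
#' match the configured population means up to Monte-Carlo error.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return Data frame with columns `id`, `IGF1`, `IL6`, `cohort` (factor) and
#'   attributes `cutoffs` and `spec`.
#' @export
generate_population <- function(spec = population_spec(), seed = 1L) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(seed)
  gR <- spec$igf1$range; iR <- spec$il6$range
  cG <- spec$cutoff_IGF1; cI <- spec$cutoff_IL6
  boxes <- list(
    highIGF_lowIL6  = list(G = c(cG, gR[2]), I = c(iR[1], cI)),
    highIGF_highIL6 = list(G = c(cG, gR[2]), I = c(cI, iR[2])),
    lowIGF_lowIL6   = list(G = c(gR[1], cG), I = c(iR[1], cI)),
    lowIGF_highIL6  = list(G = c(gR[1], cG), I = c(cI, iR[2]))
  )
  parts <- lapply(.COHORT_LEVELS, function(lb) {
    k <- spec$counts[[lb]]
    bx <- boxes[[lb]]
    G <- .tnorm_sample(k, spec$igf1$mu, spec$igf1$sd, bx$G[1], bx$G[2])
    I <- .tlnorm_sample(k, spec$il6$meanlog, spec$il6$sdlog, bx$I[1], bx$I[2])
    data.frame(IGF1 = G, IL6 = I, cohort = lb)
  })
  out <- do.call(rbind, parts)
  out <- data.frame(id = seq_len(nrow(out)), out)
  out$cohort <- factor(out$cohort, levels = .COHORT_LEVELS)
  structure(out, cutoffs = c(IGF1 = cG, IL6 = cI), spec = spec, seed = seed)
}

#' Generate the biomarker trend fixture
#'
#' Linear five-year mean time courses of the two biomarkers, anchored at the
#' population baseline means with the literature annual slopes; this is the
#' series the inhibition-strength fit consumes.
#'
#' @param baseline_IGF1,baseline_IL6 month-0 means (ng/ml, pg/ml).
#' @param slope_IGF1,slope_IL6 annual rates of change (ng/ml per year,
#'   pg/ml per year).
#' @param horizon horizon in months (monthly grid `0:horizon`).
#' @param noise_sd optional length-2 Gaussian noise SD `c(IGF1, IL6)`;
#'   the default 0 gives the exact lines.
#' @param seed seed used when noise is requested.
#' @return A `trend_fixture`: data frame `time`, `IGF1`, `IL6`.
#' @export
generate_trend_fixture <- function(baseline_IGF1 = 107.8, baseline_IL6 = 3.14,
                                   slope_IGF1 = -1.95, slope_IL6 = 0.05,
                                   horizon = 60, noise_sd = c(0, 0), seed = 1L) {
  stopifnot(horizon > 0)
  t <- 0:horizon
  G <- baseline_IGF1 + slope_IGF1 * t / 12
  I <- baseline_IL6 + slope_IL6 * t / 12
  if (any(noise_sd > 0)) {
    set.seed(seed)
    G <- G + stats::rnorm(length(t), 0, noise_sd[1])
    I <- I + stats::rnorm(length(t), 0, noise_sd[2])
  }
  if (any(G < 0) || any(I < 0)) {
    warning("projected concentrations fell below zero; truncated at 0")
    G <- pmax(G, 0); I <- pmax(I, 0)
  }
  structure(data.frame(time = t, IGF1 = G, IL6 = I),
            class = c("trend_fixture", "data.frame"),
            baselines = c(IGF1 = baseline_IGF1, IL6 = baseline_IL6),
            slopes = c(IGF1 = slope_IGF1, IL6 = slope_IL6), seed = seed)
}

#' Generate per-cohort outcome fixtures
#'
#' Builds the four cohort survival/disability series the outcome-rate fit
#' consumes. Survival is Gompertz,
#' \eqn{S_c(t) = \exp(-(a_c/b)(e^{bt} - 1))}, with a common shape `b` and
#' cohort-specific levels `a_c` determined by (i) the best cohort's five-year
#' cumulative mortality, (ii) the configured extreme-cohort cumulative
#' mortality ratio at 60 months (intermediate cohorts interpolated
#' geometrically), and (iii) the pooled (count-weighted) survival reaching
#' `extinction_tol` at `longevity_horizon` (solved for `b`).
#'
#' @param counts per-cohort sizes (risk order as [population_spec()]).
#' @param mortality_ratio extreme-cohort 60-month cumulative mortality ratio
#'   (worst/best); must be >= 1.
#' @param q60_best best-cohort 60-month cumulative mortality fraction.
#' @param horizon fixture series horizon (months).
#' @param longevity_horizon pooled extinction time (months).
#' @param extinction_tol pooled survival defining "extinct".
#' @param md0,md36 disabled fractions among survivors at months 0 and 36,
#'   one per cohort in risk order (best to worst must be non-decreasing).
#' @return List of four `cohort_outcome_fixture` objects (one per stratum):
#'   each a list with `label`, `n`, `time`, `survival`, `md_frac0`,
#'   `md_frac36`; the list carries the solved Gompertz parameters as
#'   attributes.
#' @export
generate_outcome_fixtures <- function(counts = c(highIGF_lowIL6 = 398L,
                                                 highIGF_highIL6 = 128L,
                                                 lowIGF_lowIL6 = 142L,
                                                 lowIGF_highIL6 = 50L),
                                      mortality_ratio = 2.5,
                                      q60_best = 0.10,
                                      horizon = 60,
                                      longevity_horizon = 240,
                                      extinction_tol = 1e-3,
                                      md0 = c(0.05, 0.10, 0.15, 0.30),
                                      md36 = c(0.10, 0.30, 0.40, 0.80)) {
  if (mortality_ratio < 1) stop("mortality_ratio must be >= 1")
  if (q60_best <= 0 || q60_best * mortality_ratio >= 1)
    stop("infeasible q60_best/mortality_ratio combination")
  if (is.unsorted(md0) || is.unsorted(md36))
    stop("disabled fractions must be monotone in cohort risk order")
  labs <- .COHORT_LEVELS
  # cumulative 60-month mortality per cohort, geometric between the extremes
  q60 <- q60_best * mortality_ratio^(c(0, 1, 2, 3) / 3)
  H60 <- -log(1 - q60)              # cumulative hazards at 60 months
  w <- counts / sum(counts)
  pooled240 <- function(b) {
    a <- b * H60 / expm1(b * horizon)
    max(sum(w * exp(-(a / b) * expm1(b * longevity_horizon))), 1e-300)
  }
  b <- stats::uniroot(function(b) log(pooled240(b)) - log(extinction_tol),
                      interval = c(1e-5, 0.2), tol = 1e-14)$root
  a <- b * H60 / expm1(b * horizon)
  t <- 0:horizon
  out <- lapply(seq_along(labs), function(i) {
    structure(list(label = labs[i], n = unname(counts[i]), time = t,
                   survival = exp(-(a[i] / b) * expm1(b * t)),
                   md_frac0 = md0[i], md_frac36 = md36[i]),
              class = "cohort_outcome_fixture")
  })
  names(out) <- labs
  structure(out, gompertz = list(a = stats::setNames(a, labs), b = b),
            mortality_ratio = mortality_ratio, q60_best = q60_best,
            longevity_horizon = longevity_horizon,
            extinction_tol = extinction_tol,
            class = "cohort_outcome_fixtures")
}

#' @export
print.cohort_outcome_fixtures <- function(x, ...) {
  cat("Cohort outcome fixtures (Gompertz survival):\n")
  for (f in x)
    cat(sprintf("  %-16s n = %3d  S(60) = %.4f  MD-frac 0/36 mo: %.2f / %.2f\n",
                f$label, f$n, f$survival[length(f$survival)],
                f$md_frac0, f$md_frac36))
  g <- attr(x, "gompertz")
  cat(sprintf("  shape b = %.5g /mo; pooled S(%d mo) = %g\n", g$b,
              attr(x, "longevity_horizon"), attr(x, "extinction_tol")))
  invisible(x)
}
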