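---
title: "A bistable toggle-switch model of frailty biomarkers and mobility outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bistable toggle-switch model of frailty biomarkers and mobility outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifrail)
```

## The model

`bifrail` implements a deterministic model of frailty progression in older
adults built on two mutually inhibitory serum biomarkers: insulin-like growth
factor 1 (IGF-1, `G`, in ng/ml, equivalently mcg/L) and interleukin-6 (IL-6,
`I`, in pg/ml). Each biomarker is produced at a constant rate, inhibited by a
Hill-type function of the other, and cleared first-order (time in months):

$$\frac{dG}{dt} = \frac{kp_G}{1 + ks_I I^n} - kd_G\, G, \qquad
  \frac{dI}{dt} = \frac{kp_I}{1 + ks_G G^n} - kd_I\, I .$$

With the cooperative exponent $n = 2$ this double-negative feedback loop is
the canonical genetic-toggle-switch motif: for sufficiently strong coupling
it has two stable fixed points — high IGF-1/low IL-6 and low IGF-1/high
IL-6 — separated by a saddle. Which state an individual approaches depends
only on their baseline biomarker pair, so the plane of initial conditions
splits into two basins divided by a separatrix.

The biomarkers drive three prevalence scores, deterministic fractions of
identically initialised individuals who are mobile ($M$), mobility-disabled
($MD$, walking speed below population norms) or dead ($D$):

$$\frac{dM}{dt} = -k_{loss} I M + k_{gain} G\, MD - h(t) M,$$
$$\frac{dMD}{dt} = k_{loss} I M - k_{gain} G\, MD - k_{extra} h(t) MD,$$
$$\frac{dD}{dt} = h(t)\,(M + k_{extra} MD), \qquad h(t) = k_{mort} e^{k_{longevity} t}.$$

Mortality is Gompertz-type (exponentially accelerating with time since
baseline, mean entry age 77.6 years) and does not depend on the biomarkers
directly; disability raises the hazard by the factor $k_{extra} = 2.5$. The
three scores sum to one by construction; the death equation is integrated
explicitly rather than obtained by substitution, so conservation
($\max_t |M + MD + D - 1| \le 10^{-6}$) is a genuine test of the integrator,
asserted on every simulated trajectory.

There is no feedback from clinical state to the biomarkers, and the model is
purely deterministic — no stochastic variant is provided.

## Parameters and units

| Parameter | Meaning | Units | How it is fixed |
|---|---|---|---|
| `kp_IGF1`, `kp_IL6` | production rates | ng/ml/mo, pg/ml/mo | pinned: `kp = max * kd` |
| `kd_IGF1`, `kd_IL6` | clearance rates | /mo | fit to the 5-year trend |
| `ks_IL6`, `ks_IGF1` | inhibition strengths | (pg/ml)^-2, (ng/ml)^-2 | fit to the 5-year trend |
| `hill_n` | cooperativity | – | 2 (1 for sensitivity runs) |
| `k_loss` | M→MD per unit IL-6 | /(pg/ml)/mo | fit to cohort series |
| `k_gain` | MD→M per unit IGF-1 | /(ng/ml)/mo | fit to cohort series |
| `k_mort` | baseline hazard | /mo | fit to cohort series |
| `k_longevity` | hazard acceleration | /mo | fit + 240-month horizon |
| `k_extra` | disabled-hazard amplifier | – | 2.5, literature-derived |

The physiological ceilings — the level each biomarker would reach with the
other absent — are 400 ng/ml for IGF-1 and 25 pg/ml for IL-6, from the
clinical ranges reported across ageing cohorts. Pinning `kp = max * kd`
makes these ceilings the uninhibited steady states exactly; the constraint
is structural (substituted, not penalised), so it survives any fit.

## The calibration recipe

Calibration (`fit_frailty_model()`) proceeds in two stages.

**Biomarker stage** (`fit_inhibition()`). The free parameters
`(kd_IGF1, kd_IL6, ks_IL6, ks_IGF1)` are fit by Levenberg–Marquardt
(log-transformed, positivity by construction) to the mean five-year
biomarker time courses: baselines 107.8 ng/ml and 3.14 pg/ml with linear
drifts −1.95 ng/ml and +0.05 pg/ml per year. Two facts shape the algorithm:

* *The unconstrained optimum is monostable.* A near-linear slow trend
  identifies the two slopes and little else; the least-squares valley runs
  into a corner of parameter space (`kd_IL6` → 0) where the switch loses its
  second stable state. Every free multi-start converges there.
* *Anchored retries restore bistability.* When no free start is acceptable,
  the fit holds the interior (unstable) fixed point at candidate locations
  between the baseline mean and the ceilings — the nullcline relations turn
  an anchor $(G_s, I_s)$ into exact values of the two inhibition strengths —
  and fits only the two clearance timescales per anchor. This is constrained
  least squares inside the bistable regime.

A candidate optimum is accepted only if it (i) is bistable, (ii) reproduces
the fixture's mean slopes within 10%, and (iii) honours a set of *basin
probes* encoding the qualitative phenotype structure the cohort data
demand: the majority (≥ 55% of a deterministic quantile lattice) of the
favourable high-IGF-1/low-IL-6 stratum must lie in the resilient basin, the
declining population mean must lie in the frail basin, and the switch along
initial IGF-1 at the mean IL-6 level must fall inside the observed 40–300
ng/ml range. Among accepted candidates the lowest sum of squares wins. With
the default fixtures this selects a fit whose saddle sits at roughly
(129 ng/ml, 2.6 pg/ml), just above the population mean — the population
straddles its own critical threshold, which is precisely the structure that
makes the biomarker pair informative.

**Outcome stage** (`fit_outcome_rates()`). With the biomarker parameters
frozen and `k_extra = 2.5` fixed, `(k_loss, k_gain, k_mort, k_longevity)`
are fit jointly to the four cohort fixtures: monthly survival over 60
months, the disabled fraction among survivors at 36 months, and one strongly
weighted residual pinning pooled (count-weighted) survival to $10^{-3}$ at
240 months. Each cohort is represented by a single trajectory from its
stratum mean biomarker pair with the fixture's baseline disabled fraction.
Residuals are scaled per block (0.01 survival fraction, 0.02 disabled
fraction, 0.05 log10 units of pooled survival) so no block dominates.

The longevity constraint enters the fit as a residual rather than by
eliminating `k_longevity` through the closed form
$M(t) = \exp(-(k_{mort}/k_{longevity})(e^{k_{longevity}t}-1))$, because the
closed form ignores the amplified hazard of the disabled compartment and
would bias the extinction time; `calibrate_longevity()` (the closed-form
scalar root-find) supplies the starting value.

**Identifiability.** Once disability kinetics are fast, only the
`k_loss`/`k_gain` *ratio* is identified — the likelihood has a flat ridge
along their common scale on which unbounded fits drift to arbitrarily stiff
rates. The fit therefore uses box bounds keeping per-month transition rates
on the clinical assessment timescale, and finishes with coordinate descent
along the ridge's natural axes (joint log-scale and log-ratio directions),
where Levenberg–Marquardt stalls. The biomarker stage has the analogous
property: noise-free self-generated fixtures are recovered essentially
exactly (the global optimum coincides with the truth), but under
measurement noise only the fitted *curves* and slopes are stable — raw
`(kd, ks)` scatter along a sloppy direction. The test suite asserts recovery
accordingly: parameters to 5% in the noise-free case, curves and slopes (not
raw parameters) under 5% multiplicative noise.

## Synthetic data

No individual-level data are redistributed; every input is generated
(`generate_population()`, `generate_trend_fixture()`,
`generate_outcome_fixtures()`) from summary constants, and all generators
are pure functions of (specification, seed).

* **Population** (n = 718): IGF-1 truncated normal (sd 45) on 15–315 ng/ml;
  IL-6 log-normal (sdlog 0.6, right-skewed as cytokines are) truncated to
  0.4–20 pg/ml. Location parameters are solved so the truncated means equal
  the published 107.8 ng/ml and 3.14 pg/ml exactly. The four strata
  (398/128/142/50: high-IGF/low-IL6, high/high, low/low, low/high) are
  sampled with exact counts from the marginals restricted to each stratum
  rectangle; the cut-offs are the marginal quantiles implied by the counts
  (IGF-1 low = bottom 192/718, IL-6 high = top 178/718). The printed 2×2
  counts are near-independent (odds ratio 1.10), so independent marginal
  sampling per rectangle is coherent.
* **Trend fixture**: the exact linear five-year series (noise optional).
* **Outcome fixtures**: Gompertz survival per cohort with a common shape and
  cohort levels set by three constraints — the best cohort's five-year
  cumulative mortality (0.10, a chosen constant, realistic for the
  healthiest stratum of women with mean age 77.6), the published 2.5×
  worst/best cumulative mortality ratio at 60 months (intermediate cohorts
  interpolated geometrically), and pooled extinction to $10^{-3}$ at 240
  months (solved for the shape). Baseline disabled fractions are
  (0.05, 0.10, 0.15, 0.30) by risk order; the 36-month disabled-among-
  survivor fractions (0.10, 0.30, 0.40, 0.80) rise steeply because a
  `k_extra = 2.5` hazard model can only express a 2.5× cumulative mortality
  ratio if the high-risk stratum is predominantly disabled — the fixture
  family is kept realisable by the model that will be calibrated to it.

What the generator does *not* emulate: within-person longitudinal biomarker
noise, covariates beyond the two biomarkers, informative censoring, or any
correlation structure between baseline biomarkers beyond the stratum
rectangles. Passing tests therefore demonstrate internal consistency of the
pipeline under the published summary constants, not fidelity to
individual-level cohort data.

## Numerical choices

* Integrator: `deSolve::lsoda` (stiff-capable, adaptive), rtol $10^{-8}$,
  atol $10^{-10}$. Trajectories are classified as settled for basin
  assignment by integrating to $t = 10^4$ months, far beyond the clinical
  horizon.
* Negative-concentration guard: the right-hand side clamps excursions below
  zero smaller than $10^{-6}$ in magnitude (solver roundoff at state scale
  ~100) and raises an error beyond that, separating roundoff from genuine
  model violations.
* Steady states: the two nullclines are composed into one scalar equation in
  the IGF-1 coordinate; sign changes are bracketed on an 800-point grid,
  polished by Brent's method, deduplicated, and classified by the 2×2
  Jacobian's eigenvalues. The test suite checks this against a brute-force
  2000-point dense-scan bisection oracle on 100 random parameter sets.
* Attractor assignment: relative Euclidean distance in log-concentration
  space (scale-free across the 25 pg/ml vs 400 ng/ml disparity), threshold
  1%; unassigned nodes are flagged, never dropped.
* Separatrix: per fixed-IL-6 scan line, bisection over initial IGF-1 to 0.1%
  of the axis range; single-basin lines are omitted and recorded. Default 25
  lines; the default attractor grid is 60×60 and switch sweeps use 400
  points (tests and examples use smaller grids — 8–15 lines, 100–200 sweep
  points — which resolve the same geometry).
* Phenotype classification: side-of-separatrix with linear interpolation
  between scan lines; the boundary band is widened per query point by the
  local interpolation uncertainty (half the critical-IGF-1 change across the
  bracketing lines), since the curve is steep where IL-6 is high.
* Ties and degenerate inputs: individuals exactly on a stratum cut-off go to
  the lower stratum; `k_longevity = 0` falls back to the exponential limit
  (`expm1` keeps the general formula accurate to $10^{-12}$); zero rates
  switch pathways off and are legal parameter values.

## The mobility switch under mortality

Sweeping the initial level of one biomarker (the other fixed at its
population mean) and reading mobility at 5, 20 and 30 years reproduces the
switch-like dependence of outcomes on baseline biomarkers. Two subtleties:

* Because pooled survival is calibrated to reach $10^{-3}$ at 240 months,
  the *raw* mobility score at 20–30 years is microscopic everywhere and no
  longer marks the basin boundary. Threshold detection therefore uses the
  survivor-conditioned mobile fraction $M/(M+MD)$, which the package
  integrates as its own ODE state (its dynamics,
  $\dot\varphi = -k_{loss} I \varphi + k_{gain} G (1-\varphi) +
  (k_{extra}-1) h(t) \varphi(1-\varphi)$, are independent of the absolute
  survival level and remain well-conditioned past extinction). Raw M is
  retained in the returned curve.
* Mortality censors the slow near-separatrix transients: individuals near
  the critical threshold die before their frailty fully develops, so the
  finite-horizon switch is smoothed and its midpoint sits below the
  asymptotic basin boundary (about 131 vs 181 ng/ml at 30 years for the
  default calibration). The switch still sharpens monotonically with
  horizon (steepness = the maximum interior gradient of the conditioned
  score), and in the mortality-free limit the long-horizon threshold
  converges to the separatrix crossing within one sweep step — the test
  suite asserts exactly that correspondence.

## Known limitations

* The published fitted rate constants were never printed, so absolute
  parameter values here are this package's own calibration under the
  published constraints; only ratios, slopes, counts, horizons and
  qualitative structure are comparable.
* The calibrated model compresses the extreme-cohort five-year cumulative
  mortality ratio to about 1.5 against the 2.5 encoded in the fixtures.
  Cohort hazards differ only through disabled-compartment occupancy
  (amplifier $1 + 1.5\,\mathrm{MDfrac}$), and with baseline biomarker pairs
  differing by only ~2.5× between extreme strata, a quasi-static M/MD
  balance caps the ratio near 1.5 for any `(k_loss, k_gain)`. Exceeding it
  would need the cohorts' biomarkers to diverge to their attractors well
  inside the 60-month window — clearance rates incompatible with the slow
  linear five-year mean trend. This is a structural property of the model
  class under the stated constraints, reported as measured.
* Under the same trend constraint the high-IGF/high-IL6 stratum mean
  classifies frail; a calibration in which that individual eventually
  recovers mobility (as the published envelope figures suggest) is not
  reachable jointly with the declining population mean.
* No SBML export; the exchange formats are annotated JSON (parameters,
  calibration results) and tidy CSV (trajectories, scans, curves).
* One-individual-per-stratum representation: cohorts are calibrated through
  their mean-baseline trajectories, matching the hypothetical-individual
  framing, not through per-individual simulation of the full population.

## A minimal session

```{r, eval = FALSE}
pop <- generate_population(population_spec(), seed = 1)
strata <- stratify_population(pop)
fit <- fit_frailty_model(generate_trend_fixture(),
                         generate_outcome_fixtures(),
                         as.data.frame(strata), seed = 1)
summary(fit)
plot(fit)                                     # nullclines + fixed points
sep <- find_separatrix(fit$biomarker)
classify_phenotype(pop, sep)                  # per-individual phenotype calls
mobility_switch_curve("IGF1", fit$biomarker, fit$outcome)
run_pipeline("results", pipeline_config())    # everything, to disk
```
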