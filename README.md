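# bifrail — bistable toggle-switch modelling of frailty biomarkers

`bifrail` is an R package for deterministic modelling of frailty and
mobility-disability trajectories in older adults from a pair of mutually
inhibitory serum biomarkers: insulin-like growth factor 1 (IGF-1, favouring
maintained mobility) and interleukin-6 (IL-6, an inflammatory cytokine
favouring decline). It is aimed at quantitative ageing researchers and
systems biologists who want a mechanistic, simulation-based alternative to
purely statistical risk models of frailty.

## The model

The biomarkers form a Hill-type double-negative feedback loop (time in
months, IGF-1 `G` in ng/ml, IL-6 `I` in pg/ml):

    dG/dt = kp_G / (1 + ks_I I^2) − kd_G G
    dI/dt = kp_I / (1 + ks_G G^2) − kd_I I

With cooperative inhibition (Hill coefficient 2) this is the classic genetic
toggle switch: two stable states — high IGF-1/low IL-6 (resilient) and low
IGF-1/high IL-6 (frail) — separated by a saddle, with a separatrix dividing
the plane of baseline biomarker pairs into two basins. The biomarkers drive
prevalence scores for being mobile (M), mobility-disabled (MD) or dead (D),
with M + MD + D = 1 and a Gompertz-type time-accelerating hazard that is
`k_extra = 2.5`-fold higher in the disabled state:

    dM/dt  = −k_loss I M + k_gain G MD − k_mort e^(k_longevity t) M
    dMD/dt = +k_loss I M − k_gain G MD − k_extra k_mort e^(k_longevity t) MD
    dD/dt  =  k_mort e^(k_longevity t) (M + k_extra MD)

The package provides the calibration of all eleven rate constants against
literature-derived constraints (physiological ceilings 400 ng/ml and
25 pg/ml; five-year mean trends −1.95 ng/ml/yr and +0.05 pg/ml/yr from
baselines 107.8 ng/ml and 3.14 pg/ml; four biomarker strata of a 718-woman
cohort with counts 398/128/142/50; a 2.5× extreme-cohort five-year mortality
ratio; population extinction by 240 months), plus steady-state enumeration
with stability classification, basin-of-attraction scans, separatrix
location, switch-curve analysis, cohort outcome envelopes, per-individual
phenotype classification, and generators for every synthetic input.

## Worked example

```r
library(bifrail)

pop    <- generate_population(population_spec(), seed = 1)
strata <- stratify_population(pop)
fit    <- fit_frailty_model(generate_trend_fixture(),
                            generate_outcome_fixtures(),
                            as.data.frame(strata), seed = 1)
print(fit)
```

```
Calibrated bistable frailty model
  bistable: TRUE

Biomarker toggle-switch parameters (time unit: month)
  IGF-1: kp = 6.49348 ng/ml/mo, kd = 0.0162337 /mo, ks_IL6 = 0.311763 (pg/ml)^-2
  IL-6 : kp = 0.186121 pg/ml/mo, kd = 0.00744485 /mo, ks_IGF1 = 0.00051695 (ng/ml)^-2
  uninhibited maxima: IGF-1 400 ng/ml, IL-6 25 pg/ml; Hill n = 2

Mobility/mortality parameters (time unit: month)
  k_loss = 1.25415, k_gain = 0.119039, k_mort = 0.0010653, k_longevity = 0.0193844, k_extra = 2.5

3 biomarker fixed point(s):
  IGF-1 =     2.051 ng/ml, IL-6 =     24.95 pg/ml  [stable]
  IGF-1 =     129.4 ng/ml, IL-6 =      2.59 pg/ml  [saddle]
  IGF-1 =     387.8 ng/ml, IL-6 =    0.3175 pg/ml  [stable]
```

The fit is bistable with its stable states near the physiological ceilings
(IGF-1 388 of 400 ng/ml; IL-6 24.9 of 25 pg/ml) and the saddle just above
the population mean baseline (107.8, 3.14) — the population straddles its
own critical threshold. Downstream analyses read directly off the fit:

```r
find_separatrix(fit$biomarker)
```

```
Separatrix: 8 boundary points, IL-6 in [1.38, 4] pg/ml
  critical IGF-1 from 51.81 to 284.1 ng/ml (tol 0.26 ng/ml)
  17 single-basin scan line(s) omitted
```

so at an IL-6 of 2 pg/ml an initial IGF-1 of roughly 90 ng/ml separates
lifelong-mobile from declining individuals, while above ~4 pg/ml of IL-6 no
IGF-1 level in the observed 40–300 ng/ml range rescues mobility. The
mobility switch sharpens with horizon (steepness is the maximum interior
gradient of mobility-among-survivors along the sweep):

```r
mobility_switch_curve("IGF1", fit$biomarker, fit$outcome, n = 200)
```

```
Switch curve: initial IGF1 swept over [40, 300] (IL-6 fixed at 3.14)
 horizon  critical   steepness
      60  43.26633 0.007558381
     240 105.97990 0.009400011
     360 138.64322 0.014376174
```

`run_pipeline("results", pipeline_config())` executes the whole analysis —
generation, calibration, scans, separatrix, switch curves, cohort envelopes,
phenotype calls — and writes CSV/JSON artefacts plus a machine-readable
`summary.json`, all reproducible from the configuration and seed alone.

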