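# pehr

Prolonged elevated heart rate (peHR) and 90-day mortality in ICU cohorts.

## What this package is for

Sustained tachycardia is a candidate prognostic marker in critically ill
patients, including those with acute pancreatitis. `pehr` implements the
full observational-analysis pipeline used to study that question on
hourly ICU heart-rate data, for biostatisticians and intensivists who
want a tested, reusable and fully reproducible implementation:

1. **Episode detection** on hourly median heart-rate series. The
   standard exposure definition is at least 11 hourly medians strictly
   above 100 bpm within any 12 consecutive hours; an **extended**
   definition additionally classifies as exposed patients who die while
   persistently tachycardic before a full window can complete, guarding
   against informative truncation by death. A sensitivity
   (standard-only) mode is built in.
2. **Cohort rules**: length of stay > 24 h, exclusion above 20% missing
   hourly bins, variable screening above 10% missingness, and
   predictive-mean-matching imputation.
3. **Survival analysis**: Kaplan–Meier curves with Greenwood variance,
   log-rank tests, and Cox proportional-hazards models
   `h(t | x) = h0(t) exp(β_peHR·peHR + βᵀx)` reported as hazard ratios
   with Wald 95% CIs.
4. **Propensity-score methods**: logistic propensity model, greedy 1:1
   nearest-neighbour matching within a caliper of 0.2 × SD(logit PS),
   inverse-probability weighting, and standardized-mean-difference
   balance diagnostics (crude / matched / weighted).
5. **Sensitivity grid**: the exposure is re-derived and a minimally
   adjusted Cox model refit for every heart-rate threshold (90–120 bpm)
   × duration (6–16 h) combination, with positive-set monotonicity
   checked across the grid.

Because the source databases for such studies are access-restricted, the
package ships a **synthetic-cohort generator** (`simulate_cohort()`)
with known ground truth — confounded exposure assignment, a
proportional-hazards survival model (default exposure HR 1.98),
irregular noisy heart-rate streams with injected sustained-tachycardia
episodes, hour-level missingness, and deaths that truncate ongoing
episodes. Every stage is tested end-to-end against that ground truth and
against independent oracles (a brute-force window-enumeration detector,
a hand-enumerated Cox partial likelihood, closed-form exponential
survival).

## Worked example

```r
library(pehr)

cfg <- pipeline_config(sim = sim_config(n_patients = 745, seed = 2024))
run <- run_pipeline(cfg)           # add out_dir = "out" to write the CSV bundle
print(run)
```

```
peHR pipeline run
  cohort: 745 in, 735 retained, 10 excluded
  peHR: 325 standard + 14 extended = 339 of 735 (46.1%)
  90-day survival: 84.1% (no peHR) vs 73.2% (peHR); log-rank p = 0.000258
  crude HR 1.80 (1.31-2.49); adjusted HR 1.52 (1.08-2.14)
  matched: 257 pairs, max post-match SMD 0.040; matched survival 86.8% vs 76.7%
  grid: 77 cells, 0 monotonicity violations
```

Reading the output: of 745 simulated admissions, 735 pass the inclusion
filters; 46.1% are classified peHR-positive (325 by a full qualifying
window, 14 by the death-truncated extension). The exposed group has
markedly lower 90-day survival; the crude hazard ratio (1.80) shrinks
toward the adjusted one (1.52) once the built-in confounding by age,
SOFA and ventilation is adjusted away, and after 1:1 propensity matching
all covariate imbalances fall below SMD 0.1 while the survival gap
persists. At this cohort size the adjusted estimate is attenuated below
the generating HR of 1.98 because detection from noisy, gappy vitals
misclassifies ~8% of true exposures — see the methods vignette.

```r
print(run$cox_multivariate)
```

```
Cox proportional-hazards fit (efron ties): n = 735, events = 154
        term    HR          CI       p
    exposure 1.522 1.083-2.139 1.6e-02
         age 0.993 0.984-1.002 1.4e-01
        sofa 1.049 1.015-1.084 4.6e-03
         map 1.002 0.990-1.014 7.4e-01
 temperature 1.161 0.861-1.566 3.3e-01
      sepsis 2.131 1.542-2.945 4.6e-06
 ventilation 1.200 0.864-1.666 2.8e-01
```

Each stage is also available standalone — `simulate_cohort()`,
`hourly_medians()`, `apply_inclusion_filters()`, `pmm_impute()`,
`detect_standard()` / `detect_extended()` / `classify_cohort()`,
`km_fit()` / `logrank_test()` / `cox_fit()`, `estimate_propensity()` /
`nn_match()` / `ipw_weights()` / `smd_table()`, and `run_grid()` /
`check_monotonicity()`. Configurations round-trip through flat YAML via
`read_config()` / `write_config()`.

## Vignette

`vignettes/pehr-methods.Rmd` documents the data-generating model and its
calibration, every detection and filtering convention, the numerical
choices, and known limitations.
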