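---
title: "Methods: prolonged elevated heart rate and 90-day mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prolonged elevated heart rate and 90-day mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Sustained tachycardia in critically ill patients is a plausible marker —
and possibly a mediator — of poor outcome. `pehr` implements a complete,
reproducible analysis of the association between *prolonged elevated heart
rate* (peHR) and 90-day mortality in an ICU cohort, of the kind performed
on electronic health-record databases for patients with acute
pancreatitis. The exposure is defined on the hourly median heart-rate
series:

* **standard definition** — at least 11 hourly medians strictly above
  100 bpm within any 12 consecutive hours;
* **extended definition** — a patient who dies while persistently
  tachycardic, before a full qualifying window can accumulate, is also
  classified exposed. This guards the exposure against informative
  truncation by death: the sickest tachycardic patients would otherwise
  be classified unexposed *because* they died quickly.

Because the source data for such studies (credentialed ICU EHR databases)
cannot be redistributed, the package is built around a synthetic-cohort
generator with known ground truth. Every downstream stage — ingestion,
filtering, imputation, detection, survival modelling, propensity-score
analysis and the threshold×duration sensitivity grid — is exercised and
tested end-to-end on data whose generating parameters are known exactly.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` produce three linked tables: a
long-format vitals stream, a patient covariate/outcome table and a
ground-truth table. The generator's defaults are the study conditions of
the motivating cohort; they are fixed once and are not tuning knobs.

**Covariates.** Marginals are shaped after the published baseline table
of the motivating cohort: age ~ truncated normal (median ≈ 58 y), weight
~ log-normal (median ≈ 82 kg), SOFA ~ discretized gamma (median ≈ 5),
MAP, temperature and SpO2 ~ truncated normals, and Bernoulli comorbidity,
sepsis (40%), ventilation (51%), vasopressor (36%) and β-blocker (35%)
flags. Only marginal shapes matter for exercising the pipeline; no
inter-covariate correlation is modelled.

**Exposure assignment.** True exposure (an injected sustained-tachycardia
episode) follows a logistic model in age (−0.035 per year), SOFA (+0.08
per point) and ventilation (+0.85), with the intercept solved numerically
so the marginal prevalence equals `episode_prevalence` (default 0.489).
This reproduces the qualitative baseline imbalance of the motivating
cohort — exposed patients are younger, sicker and more often ventilated —
so the propensity-score machinery has genuine confounding to remove.

**Survival.** 90-day survival comes from a proportional-hazards model
with constant (exponential) baseline hazard:
hazard = `baseline_hazard` × exp(Σ β(x − x̄) + β_peHR × exposure).
Defaults: β_peHR = ln(1.98) (the adjusted estimate of the motivating
study, used as generating truth), SOFA ln(1.05)/point, sepsis ln(1.53),
ventilation ln(1.21), age 0 — the multivariable column of the motivating
study's Cox table. Effects are centred at the generator's covariate
means, so `baseline_hazard` is the hazard of a covariate-average
unexposed patient; its default, −log(0.845)/90 per day, is calibrated to
the 84.5% unexposed 90-day survival of the motivating cohort. The
exponential choice is deliberate: it is the simplest PH-compatible
generator and admits closed-form checks (S(90) = 0.5 when the rate is
ln 2/90). Latent times are shifted by 26 h inside `simulate_cohort()`;
for an exponential this is exact conditioning on surviving the first
26 h (memorylessness), it guarantees every subject clears the strict
">24 h length of stay" inclusion rule, and — being a common monotone
shift — leaves the rank-based Cox estimand untouched.

**Vitals.** Measurement timestamps follow a homogeneous Poisson-style
counting process (default 3 samples/h) with uniform placement within the
hour: irregular charting without modelling nurse workflows. Values are a
truncated-normal baseline (mean 85, sd 8, truncated to [55, 95] bpm so
that ground truth is unambiguous) plus the episode amplitude (mean 30,
sd 5 bpm) inside the injected interval, plus N(0, 5²) measurement noise.
Episode amplitudes are truncated below so the plateau clears
`episode_floor` (106 bpm): an injected "sustained tachycardia" that never
crosses the 100 bpm threshold would make the ground-truth label
meaningless. Whole hours are then deleted completely at random at
`missing_hour_rate` (default 5%); together with hours that simply receive
no samples this produces realistic hour-level gaps for the missingness
filter to act on.

**Deaths during episodes.** Deaths within `icu_death_cap_days` (28 d)
occur in the ICU: the stay extends (or shortens) to the hour of death and
the vitals stream is truncated there. Without this front-loading, an
exponential 90-day death process combined with median ICU stays of ~3
days leaves almost no deaths inside the ICU and the extended-definition
pathway untested. An exposed subject dying in the ICU dies *during* the
injected episode with probability `death_truncation_prob` (0.6,
reflecting that in the motivating cohort nearly all tachycardic
in-hospital decedents were persistently tachycardic up to death); the
elevated run before death is drawn as 3–9 h — capped at 9 because the
partially observed death hour contributes one further elevated bin, and a
10-hour run plus that bin would already complete an 11-of-12 window and
wrongly satisfy the standard definition.

**What the generator does not emulate.** Real charting patterns (q1h
nursing documentation aligned to clock hours), inter-vital correlation,
treatment feedback (β-blockade lowering heart rate), informative
missingness, and non-constant baseline hazards. Passing tests therefore
demonstrate the *pipeline's* correctness under a known data-generating
process, not the clinical findings' robustness to real-data pathologies.

## Ingestion rules

* Hour bins are half-open intervals [k, k+1) hours from each patient's
  own admission; bin values are sample medians (even counts average the
  two central values).
* Inclusion requires length of stay strictly greater than 24 h;
  exclusion requires strictly more than 20% missing hourly bins over the
  span from admission to last observation (or death). The observed-span
  denominator avoids penalizing early discharge. All boundaries are
  strict and boundary-tested (exactly 24 h is excluded; exactly 20%
  missing is retained).
* Covariates missing in more than 10% of subjects are dropped (exactly
  10% is retained); the remainder are completed by single-imputation
  predictive mean matching (Type-1: donors selected by predicted-value
  distance, 5 donors by default, all ties at the k-th distance admitted
  to the pool). Single rather than multiple imputation because the
  pipeline reports point estimates; imputed values always lie in the
  observed support and observed cells are never altered.

## Detection conventions

Exceedance is strict (`> 100`, not `≥`), so a series pinned exactly at
the threshold is negative. Missing bins count as non-exceedance: an
episode is never declared from unobserved hours, and the ≤20% missingness
filter bounds the resulting insensitivity. Windows must fit entirely
inside the observed span; a span shorter than the window is negative (and
flagged), not an error. The extended definition requires death plus an
unbroken observed elevated run of at least `min_terminal_run` (default
3 h) ending at the last bin before death (one trailing missing bin
tolerated); 3 h is a conservative floor for "persistently elevated
leading up to death" — the definition's source gives no run length — and
the parameter is exposed in configuration. Standard status always takes
precedence over extended. A brute-force window-enumeration oracle
(`detect_standard_oracle()`) ships with the package and the suite checks
exact agreement on randomized series.

## Survival analysis, matching, grid

Kaplan-Meier, log-rank and Cox fits are delegated to the survival
package; `pehr` adds the domain conventions: administrative censoring at
90 days before fitting, Efron tie handling by default (day-granularity
endpoints produce heavy ties; Breslow available by flag), Wald 95%
intervals and p-values (matching the HR/CI/p presentation of clinical
tables, and making "CI excludes 1 iff p < 0.05" exact by construction).
The hand-enumerated partial likelihood appears only as a test oracle on
tiny datasets.

The propensity model is logistic in age, ventilation and SOFA — the
covariate list replaces the vaguely specified variable-importance step of
the motivating analysis with its own published conclusion. Matching is
greedy 1:1 nearest-neighbour without replacement on the logit propensity
score, processed in seeded random order, with caliper 0.2 × SD(logit PS)
(the conventional reading of "0.2 logits of the standard difference").
Inverse-probability weights (ATE, optionally stabilized) are provided as
the companion diagnostic path; both share the propensity model, and
standardized mean differences are reported crude, matched and weighted
(binary covariates use the proportion-based pooled variance).

The sensitivity grid maps duration d to the rule "at least d elevated
hours within d+1 consecutive hours", generalizing the 11-of-12 pattern by
preserving its one-hour tolerance; whether the original raster used
"d of d+1" or "d of d" is unstated, and this mapping is a declared
design choice. Thresholds default to 90–120 bpm in 5 bpm steps and
durations to 6–16 h. Each cell refits a minimally adjusted Cox model
(exposure + age + ventilation + SOFA); constant-exposure or failed cells
are emitted with a reason code, never dropped, and positive-set
containment across adjacent cells is asserted on every grid run.

## Group comparisons

Continuous variables display median (IQR) while the default test is the
t-test — mirroring the (internally tense) convention of the motivating
report; a flag switches to the rank-sum test and the table names the test
used per row. Categorical variables use the continuity-corrected
chi-square for 2×2 tables: on the motivating study's in-hospital
mortality cells this is the variant that reproduces the published
p-value, which settled the default. Larger tables use the uncorrected
Pearson statistic; any expected count below 1 routes to Fisher's exact
test.

## Numerical choices and degenerate inputs

* Cox convergence: relative log-likelihood tolerance 1e-9, at most 100
  iterations; singular information or detected separation is an error
  (penalization is out of scope).
* Propensity scores within 1e-8 of 0/1 are treated as separation;
  weight trimming is out of scope.
* Equidistant PMM donors are all admitted to the sampling pool
  (unbiased under ties).
* Zero pooled variance with a nonzero mean difference yields an
  infinite SMD, reported as such.
* Operations taking a `seed` use a private RNG stream and restore the
  caller's generator state.

## Problem sizes used by the test suite

The suite validates the detector against the brute-force oracle on
10,000 randomized 72-h series across the full rule grid; grid
monotonicity on a 2,000-patient cohort over all 77 default cells;
exposure-HR recovery (generating value 1.98) over 50 replicates of
n = 2,000 with 95% CI coverage tracked; the Kaplan-Meier exponential
closed form at n = 5,000; log-rank type-I error over 2,000 null
replicates; matching balance on a 2,000-patient confounded cohort; the
constructed 312-standard/52-extended classification fixture; and byte
identity of two pipeline bundles at n = 400. These sizes were chosen so
the whole suite runs in a few minutes on one CPU while keeping Monte
Carlo error well inside the asserted bounds.

## Known limitations

* Detection sensitivity under the default noise and missingness is below
  1 (about 0.9, with essentially no false positives), so pipeline-level
  hazard ratios computed on *detected* exposure are attenuated relative
  to the generating value — visible when comparing the pipeline's
  adjusted HR with the parameter-recovery experiment, which conditions
  on true exposure. This nondifferential misclassification is a feature
  of the design, not a bug: the motivating analysis faces the same
  attenuation.
* The standard-only sensitivity classification reassigns death-truncated
  episodes to the unexposed arm; because those are early deaths, this
  depresses the estimated exposure effect substantially — which is
  precisely the informative-truncation argument for the extended
  definition.
* Exponential baseline hazard, MCAR missingness (hour level and
  covariate level) and single imputation are simplifications; a Weibull
  baseline and multiple imputation are natural extensions but out of
  scope.
* The exposure is treated as a fixed baseline-period classification; no
  time-varying exposure modelling, competing risks, or
  proportional-hazards diagnostics beyond the package's scope are
  provided.

## Interface note

The package is function-first: `run_pipeline()` plus a flat YAML
configuration (`read_config()`/`write_config()`) is the orchestration
surface, and `scripts/acceptance.R` is a thin script over the installed
package that recomputes the headline quantities from scratch. Every
stage is equally usable standalone, which is how the test suite drives
them.
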