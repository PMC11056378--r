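#' Simulation configuration for synthetic ICU cohorts
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size,
#' prevalence of true sustained-tachycardia exposure, heart-rate process
#' parameters, hour-level missingness, the proportional-hazards survival
#' model, and the mechanism that places some deaths inside an ongoing
#' episode (exercising the death-truncated "extended" exposure definition).
#'
#' Defaults encode the study conditions of the motivating ICU acute
#' pancreatitis cohort: exposure prevalence 0.489, exposure log hazard
#' ratio `log(1.98)`, hazard covariate effects taken from the multivariable
#' Cox column (SOFA 1.05 per point, sepsis 1.53, ventilation 1.21, age
#' null), and a baseline hazard calibrated so an unexposed reference
#' patient has 84.5% 90-day survival. The exposure-assignment model makes
#' younger age, higher SOFA and ventilation predict exposure, reproducing
#' the baseline-imbalance pattern of the source cohort so that propensity
#' methods have real confounding to remove.
#'
#' @param n_patients Number of subjects.
#' @param episode_prevalence Marginal probability of true exposure
#'   (an injected sustained episode); the assignment is confounded through
#'   `exposure_coefs` but calibrated to this marginal.
#' @param baseline_hr_mean,baseline_hr_sd Baseline (non-episode) heart-rate
#'   level, bpm. Baselines are truncated to \[55, 95\] bpm so that ground
#'   truth exposure is unambiguous.
#' @param episode_amplitude_mean,episode_amplitude_sd Additive elevation of
#'   heart rate during an injected episode, bpm.
#' @param episode_floor Minimum plateau (baseline + amplitude) of an
#'   injected episode, bpm; amplitudes are truncated below so an injected
#'   episode is genuinely tachycardic.
#' @param episode_duration_range Length-2 integer vector, hours; injected
#'   episode durations are drawn uniformly from this range.
#' @param measurement_rate Mean number of heart-rate measurements per hour
#'   (homogeneous Poisson-style counting process).
#' @param measurement_noise_sd Measurement noise sd, bpm.
#' @param missing_hour_rate Probability that a whole hour of measurements
#'   is discarded (missing completely at random).
#' @param covariate_missing_rate MCAR missingness rate applied to the
#'   lab-like covariates (weight, MAP, temperature, SpO2) in the patient
#'   table, to exercise variable screening and imputation.
#' @param covariate_effects Named numeric vector of log hazard ratios;
#'   effects multiply deviations from fixed reference values equal to the
#'   generator's covariate means, so `baseline_hazard` is the hazard of a
#'   covariate-average unexposed patient.
#' @param exposure_coefs Named numeric vector of log odds ratios of the
#'   exposure-assignment (confounding) model; intercept solved numerically
#'   to hit `episode_prevalence`.
#' @param exposure_log_hazard Log hazard ratio of true exposure.
#' @param baseline_hazard Baseline hazard, events/day (exponential).
#' @param horizon_days Administrative censoring horizon, days.
#' @param death_truncation_prob Probability that an exposed subject dying
#'   in the ICU dies *during* the injected episode, truncating it before a
#'   full qualifying window can complete.
#' @param icu_death_cap_days Deaths occurring within this many days happen
#'   in the ICU (the stay extends to death and the vitals stream is
#'   truncated there); later deaths occur after ICU discharge. Mirrors the
#'   front-loading of ICU deaths in critical illness.
#' @param truncation_run_range Length-2 integer vector; number of elevated
#'   hours immediately preceding a mid-episode death.
#' @param seed Integer seed; mandatory.
#'
#' @return A list of class `pehr_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 745,
                       episode_prevalence = 0.489,
                       baseline_hr_mean = 85,
                       baseline_hr_sd = 8,
                       episode_amplitude_mean = 30,
                       episode_amplitude_sd = 5,
                       episode_floor = 106,
                       episode_duration_range = c(14L, 48L),
                       measurement_rate = 3,
                       measurement_noise_sd = 5,
                       missing_hour_rate = 0.05,
                       covariate_missing_rate = 0.03,
                       covariate_effects = c(age = 0,
                                             sofa = log(1.05),
                                             sepsis = log(1.53),
                                             ventilation = log(1.21)),
                       exposure_coefs = c(age = -0.035,
                                          sofa = 0.08,
                                          ventilation = 0.85),
                       exposure_log_hazard = log(1.98),
                       baseline_hazard = -log(0.845) / 90,
                       horizon_days = 90,
                       death_truncation_prob = 0.6,
                       icu_death_cap_days = 28,
                       truncation_run_range = c(3L, 9L),
                       seed) {
  if (missing(seed) || is.null(seed))
    stop_field("seed", "a seed is mandatory")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_field("seed", "must be a single integer")
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 1)
    stop_field("n_patients", "must be >= 1")
  check_prob(episode_prevalence, "episode_prevalence")
  check_prob(missing_hour_rate, "missing_hour_rate")
  check_prob(covariate_missing_rate, "covariate_missing_rate")
  check_prob(death_truncation_prob, "death_truncation_prob")
  check_pos(horizon_days, "horizon_days")
  check_pos(icu_death_cap_days, "icu_death_cap_days", strict = FALSE)
  check_pos(baseline_hazard, "baseline_hazard", strict = FALSE)
  check_pos(measurement_rate, "measurement_rate")
  check_pos(baseline_hr_mean, "baseline_hr_mean")
  check_pos(baseline_hr_sd, "baseline_hr_sd", strict = FALSE)
  check_pos(measurement_noise_sd, "measurement_noise_sd", strict = FALSE)
  check_pos(episode_amplitude_sd, "episode_amplitude_sd", strict = FALSE)
  if (length(episode_duration_range) != 2L ||
      any(is.na(episode_duration_range)) ||
      episode_duration_range[1] > episode_duration_range[2] ||
      episode_duration_range[1] < 1 ||
      episode_duration_range[2] > horizon_days * 24)
    stop_field("episode_duration_range",
               "must be an increasing pair within [1, horizon_days*24]")
  if (!is.numeric(covariate_effects) ||
      (length(covariate_effects) && is.null(names(covariate_effects))))
    stop_field("covariate_effects", "must be a named numeric vector")
  if (!is.numeric(exposure_coefs) || is.null(names(exposure_coefs)))
    stop_field("exposure_coefs", "must be a named numeric vector")
  if (length(truncation_run_range) != 2L ||
      truncation_run_range[1] < 1 ||
      truncation_run_range[1] > truncation_run_range[2])
    stop_field("truncation_run_range", "must be an increasing pair >= 1")

  cfg <- list(
    n_patients = as.integer(n_patients),
    episode_prevalence = episode_prevalence,
    baseline_hr_mean = baseline_hr_mean,
    baseline_hr_sd = baseline_hr_sd,
    episode_amplitude_mean = episode_amplitude_mean,
    episode_amplitude_sd = episode_amplitude_sd,
    episode_floor = episode_floor,
    episode_duration_range = as.integer(round(episode_duration_range)),
    measurement_rate = measurement_rate,
    measurement_noise_sd = measurement_noise_sd,
    missing_hour_rate = missing_hour_rate,
    covariate_missing_rate = covariate_missing_rate,
    covariate_effects = covariate_effects,
    exposure_coefs = exposure_coefs,
    exposure_log_hazard = exposure_log_hazard,
    baseline_hazard = baseline_hazard,
    horizon_days = horizon_days,
    death_truncation_prob = death_truncation_prob,
    icu_death_cap_days = icu_death_cap_days,
    truncation_run_range = as.integer(round(truncation_run_range)),
    seed = as.integer(seed)
  )
  class(cfg) <- "pehr_sim_config"
  cfg
}

#' @export
print.pehr_sim_config <- function(x, ...) {
  cat("Synthetic ICU cohort configuration\n")
  cat(sprintf("  n_patients: %d   prevalence: %.3f   exposure HR: %.2f\n",
              x$n_patients, x$episode_prevalence,
              exp(x$exposure_log_hazard)))
  cat(sprintf("  baseline HR: %.0f (sd %.0f) bpm; episode amplitude: %.0f (sd %.0f), floor %.0f\n",
              x$baseline_hr_mean, x$baseline_hr_sd,
              x$episode_amplitude_mean, x$episode_amplitude_sd,
              x$episode_floor))
  cat(sprintf("  baseline hazard: %.5f /day; horizon %g d; seed %d\n",
              x$baseline_hazard, x$horizon_days, x$seed))
  invisible(x)
}

# Reference covariate values (the generator's marginal means): hazard
# effects act on (x - reference), so baseline_hazard is the hazard of a
# covariate-average unexposed patient and stays calibrated to the target
# unexposed 90-day survival.
covariate_reference <- function() {
  c(age = 59, sofa = 6, weight = 83, map = 81, temperature = 37,
    spo2 = 96.2, sepsis = 0.40, ventilation = 0.51, vasopressor = 0.36,
    beta_blocker = 0.35)
}

#' Pipeline configuration
#'
#' Analysis-stage parameters of the end-to-end pipeline. Every operational
#' constant of the analysis lives here with its study default: detection
#' rule 11-of-12 h above 100 bpm, LOS inclusion > 24 h, exclusion at > 20%
#' missing hourly bins, variable screening at > 10% missing, PMM with 5
#' donors, Austin caliper 0.2 SD of the logit propensity score, 90-day
#' horizon, and the 90-120 bpm by 6-16 h sensitivity grid.
#'
#' @param sim A [sim_config()] object (the data source for a simulated run).
#' @param hr_threshold Episode heart-rate threshold, bpm (strict `>`).
#' @param window_hours,required_hours Qualifying window: at least
#'   `required_hours` elevated hourly medians within any window of
#'   `window_hours` consecutive hours.
#' @param min_terminal_run Minimum elevated observed hours immediately
#'   preceding death for the extended (death-truncated) definition.
#' @param los_min_hours Inclusion: length of stay must strictly exceed this.
#' @param max_missing_fraction Exclusion: fraction of missing hourly bins
#'   strictly above this.
#' @param var_missing_threshold Variable screening: drop covariates whose
#'   missing fraction strictly exceeds this.
#' @param k_donors Donors for predictive mean matching imputation.
#' @param caliper_sd Caliper as a multiple of SD(logit PS).
#' @param psm_covariates Covariates of the propensity model.
#' @param cox_covariates Adjustment set of the multivariable Cox model.
#' @param grid_covariates Minimal adjustment set used per grid cell.
#' @param grid_thresholds,grid_durations Sensitivity grid axes.
#' @param horizon_days Administrative censoring horizon, days.
#' @param continuous_test `"t"` or `"wilcox"` for group comparisons.
#' @return A list of class `pehr_config`.
#' @export
pipeline_config <- function(sim = NULL,
                            hr_threshold = 100,
                            window_hours = 12L,
                            required_hours = 11L,
                            min_terminal_run = 3L,
                            los_min_hours = 24,
                            max_missing_fraction = 0.20,
                            var_missing_threshold = 0.10,
                            k_donors = 5L,
                            caliper_sd = 0.2,
                            psm_covariates = c("age", "ventilation", "sofa"),
                            cox_covariates = c("age", "sofa", "map",
                                               "temperature", "sepsis",
                                               "ventilation"),
                            grid_covariates = c("age", "ventilation", "sofa"),
                            grid_thresholds = seq(90, 120, by = 5),
                            grid_durations = 6:16,
                            horizon_days = 90,
                            continuous_test = c("t", "wilcox")) {
  continuous_test <- match.arg(continuous_test)
  check_prob(max_missing_fraction, "max_missing_fraction")
  check_prob(var_missing_threshold, "var_missing_threshold")
  check_pos(hr_threshold, "hr_threshold")
  check_pos(caliper_sd, "caliper_sd")
  check_pos(horizon_days, "horizon_days")
  if (required_hours < 1 || required_hours > window_hours)
    stop_field("required_hours", "must satisfy 1 <= required <= window")
  cfg <- list(sim = sim,
              hr_threshold = hr_threshold,
              window_hours = as.integer(window_hours),
              required_hours = as.integer(required_hours),
              min_terminal_run = as.integer(min_terminal_run),
              los_min_hours = los_min_hours,
              max_missing_fraction = max_missing_fraction,
              var_missing_threshold = var_missing_threshold,
              k_donors = as.integer(k_donors),
              caliper_sd = caliper_sd,
              psm_covariates = psm_covariates,
              cox_covariates = cox_covariates,
              grid_covariates = grid_covariates,
              grid_thresholds = grid_thresholds,
              grid_durations = as.integer(grid_durations),
              horizon_days = horizon_days,
              continuous_test = continuous_test)
  class(cfg) <- "pehr_config"
  cfg
}

#' Read / write a pipeline configuration as flat YAML
#'
#' The file is a flat key-value mapping; simulation keys (those of
#' [sim_config()]) are nested under `sim:`. Named vectors are written as
#' YAML maps.
#'
#' @param path File path.
#' @return `read_config()` returns a `pehr_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    for (nm in c("covariate_effects", "exposure_coefs"))
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    for (nm in c("episode_duration_range", "truncation_run_range"))
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    sim <- do.call(sim_config, s)
    raw$sim <- NULL
  }
  raw <- lapply(raw, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipeline_config, c(list(sim = sim), raw))
}

#' @rdname read_config
#' @param config A `pehr_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pehr_config"))
  out <- unclass(config)
  if (!is.null(out$sim)) {
    out$sim <- unclass(out$sim)
    out$sim$covariate_effects <- as.list(out$sim$covariate_effects)
    out$sim$exposure_coefs <- as.list(out$sim$exposure_coefs)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
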