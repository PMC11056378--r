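#' Simulate an irregularly sampled heart-rate stream
#'
#' Generates measurement timestamps from a homogeneous Poisson-style
#' counting process (`measurement_rate` samples/hour on average, uniform
#' within the hour) and values equal to `baseline`, plus the episode
#' amplitude inside any injected episode interval, plus Gaussian
#' measurement noise. Inside an episode interval the noise-free hourly
#' mean therefore exceeds the baseline by exactly the episode amplitude.
#'
#' @param baseline Baseline heart rate, bpm.
#' @param episodes `NULL`, or a data frame with columns `start` (hour),
#'   `duration` (hours) and `amplitude` (bpm). Episode intervals
#'   `[start, start + duration)` must not overlap.
#' @param span_hours Observation span in hours; hours are indexed
#'   `0, ..., span_hours - 1`.
#' @param config A [sim_config()] (only the measurement-process fields are
#'   used).
#' @return A data frame with columns `offset_minutes` (strictly
#'   increasing) and `heart_rate`.
#' @export
simulate_hr_series <- function(baseline, episodes = NULL, span_hours,
                               config) {
  stopifnot(inherits(config, "pehr_sim_config"))
  span_hours <- as.integer(span_hours)
  if (span_hours < 1) stop_field("span_hours", "must be >= 1")
  if (!is.null(episodes) && nrow(episodes) > 0) {
    ep <- episodes[order(episodes$start), , drop = FALSE]
    if (nrow(ep) > 1 &&
        any(ep$start[-1] < (ep$start + ep$duration)[-nrow(ep)]))
      stop("episode intervals overlap", call. = FALSE)
  } else {
    ep <- NULL
  }
  counts <- stats::rpois(span_hours, config$measurement_rate)
  if (sum(counts) == 0L) counts[1L] <- 1L  # keep at least one observation
  hour <- rep.int(seq_len(span_hours) - 1L, counts)
  offset <- (hour + sort_within(hour, stats::runif(length(hour)))) * 60
  level <- rep.int(baseline, length(hour))
  if (!is.null(ep)) {
    for (j in seq_len(nrow(ep))) {
      inside <- hour >= ep$start[j] & hour < ep$start[j] + ep$duration[j]
      level[inside] <- level[inside] + ep$amplitude[j]
    }
  }
  hr <- level + stats::rnorm(length(hour), 0, config$measurement_noise_sd)
  data.frame(offset_minutes = offset, heart_rate = hr)
}

# Sort values within runs of equal keys (keys already grouped).
sort_within <- function(key, x) {
  o <- order(key, x)
  x[o]
}

#' Draw survival times from a proportional-hazards model
#'
#' The hazard of subject i is
#' `baseline_hazard * exp(sum(beta * (x - ref)) + exposure_log_hazard * exposure)`
#' with a constant (exponential) baseline. Latent times are drawn from this
#' hazard, shifted by `min_time_days`, and administratively censored at
#' `horizon_days`. Covariate effects `beta` come from
#' `config$covariate_effects` and act on deviations from fixed reference
#' values equal to the generator's covariate means (age 59, SOFA 6, ...),
#' so `baseline_hazard` is the hazard of a covariate-average unexposed
#' patient; the centering only shifts the baseline hazard's
#' interpretation, not the estimable log hazard ratios.
#'
#' @param covariates Data frame containing every column named in
#'   `config$covariate_effects`.
#' @param exposure Logical vector, one per subject.
#' @param config A [sim_config()].
#' @param min_time_days Minimum survival time (left shift); the cohort
#'   generator uses 26/24 days so all subjects clear the 24-hour length of
#'   stay inclusion rule. By exponential memorylessness this is exact
#'   conditioning on surviving the first `min_time_days`.
#' @return A data frame with columns `time` (days) and `event` (logical).
#' @export
simulate_survival <- function(covariates, exposure, config,
                              min_time_days = 0) {
  stopifnot(inherits(config, "pehr_sim_config"))
  n <- length(exposure)
  eff <- config$covariate_effects
  missing_cov <- setdiff(names(eff), names(covariates))
  if (length(missing_cov))
    stop("covariate_effects name columns absent from covariates: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  refs <- covariate_reference()
  lp <- rep(0, n)
  for (nm in names(eff)) {
    ref <- if (nm %in% names(refs)) refs[[nm]] else 0
    lp <- lp + eff[[nm]] * (as.numeric(covariates[[nm]]) - ref)
  }
  lp <- lp + config$exposure_log_hazard * as.numeric(exposure)
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor in survival simulation", call. = FALSE)
  hazard <- config$baseline_hazard * exp(lp)
  latent <- min_time_days + stats::rexp(n) / hazard  # Inf when hazard == 0
  data.frame(time = pmin(latent, config$horizon_days),
             event = latent < config$horizon_days)
}

#' Remove whole hours of measurements at random
#'
#' Empties each (subject, hour) bin independently with probability
#' `rate` — missingness completely at random at the hour level, the
#' mechanism the downstream missing-hours exclusion rule is tested
#' against.
#'
#' @param samples Vitals data frame with `subject_id` and `offset_minutes`.
#' @param rate Probability in \[0, 1\] that an hour bin is emptied.
#' @param seed Optional seed for a private RNG stream.
#' @return `samples` with the selected hour bins removed.
#' @export
inject_missingness <- function(samples, rate, seed = NULL) {
  check_prob(rate, "rate")
  if (rate == 0 || nrow(samples) == 0) return(samples)
  with_seed(seed, {
    key <- paste(samples$subject_id, samples$offset_minutes %/% 60)
    bins <- unique(key)
    drop <- bins[stats::runif(length(bins)) < rate]
    samples[!(key %in% drop), , drop = FALSE]
  })
}

# Covariate marginals shaped after the source cohort's baseline table:
# medians/IQRs for the continuous variables, observed proportions for the
# flags. Only the marginal shapes matter for exercising the pipeline.
simulate_covariates <- function(n) {
  flags <- c(mi = 0.10, chf = 0.19, pvd = 0.06, cvd = 0.06, dementia = 0.03,
             cpd = 0.21, rheumatic = 0.03, pud = 0.05, liver = 0.28,
             diabetes = 0.06, renal = 0.18, cancer = 0.08)
  out <- data.frame(
    subject_id = seq_len(n),
    age = rtruncnorm(n, 59, 19, 18, 95),
    sex = ifelse(stats::runif(n) < 0.57, "M", "F"),
    weight = stats::rlnorm(n, log(83), 0.26),
    sofa = pmin(24, round(stats::rgamma(n, shape = 2, scale = 3))),
    map = rtruncnorm(n, 81, 13, 40, 130),
    temperature = rtruncnorm(n, 37.0, 0.55, 34, 41),
    spo2 = rtruncnorm(n, 96.2, 1.9, 80, 100)
  )
  for (nm in names(flags))
    out[[nm]] <- as.integer(stats::runif(n) < flags[[nm]])
  out$sepsis <- as.integer(stats::runif(n) < 0.40)
  out$ventilation <- as.integer(stats::runif(n) < 0.51)
  out$vasopressor <- as.integer(stats::runif(n) < 0.36)
  out$beta_blocker <- as.integer(stats::runif(n) < 0.35)
  out
}

# Confounded exposure assignment: logistic in the exposure_coefs
# covariates, intercept solved so the marginal prevalence equals
# episode_prevalence.
assign_exposure <- function(covariates, config) {
  p <- config$episode_prevalence
  n <- nrow(covariates)
  if (p == 0) return(rep(FALSE, n))
  if (p == 1) return(rep(TRUE, n))
  refs <- covariate_reference()
  lp <- rep(0, n)
  for (nm in names(config$exposure_coefs)) {
    if (!nm %in% names(covariates))
      stop("exposure_coefs name columns absent from covariates: ", nm,
           call. = FALSE)
    ref <- if (nm %in% names(refs)) refs[[nm]] else 0
    lp <- lp + config$exposure_coefs[[nm]] *
      (as.numeric(covariates[[nm]]) - ref)
  }
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) - p,
                          interval = c(-30, 30))$root
  stats::runif(n) < stats::plogis(alpha + lp)
}

#' Simulate a complete synthetic ICU cohort with known ground truth
#'
#' Draws covariates with baseline-table-like marginals, assigns true
#' sustained-tachycardia exposure through a confounded logistic model
#' calibrated to `episode_prevalence`, draws 90-day survival from the
#' configured proportional-hazards model, and (optionally) generates the
#' full irregular heart-rate stream: a truncated-normal baseline below
#' 100 bpm, one injected episode per exposed subject whose plateau clears
#' `episode_floor`, hour-level MCAR missingness, and vitals truncated at
#' in-ICU death. Exposed subjects who die in the ICU die *during* their
#' episode with probability `death_truncation_prob`, leaving an elevated
#' terminal run too short to complete a qualifying window — the ground
#' truth for the extended (death-truncated) exposure definition.
#'
#' @param config A [sim_config()]; `config$seed` drives all randomness.
#' @param vitals If `FALSE`, skip heart-rate stream generation and return
#'   only the patient and truth tables (used for covariate/survival
#'   calibration experiments where the vitals are not needed).
#' @return A list of class `pehr_cohort` with elements `vitals` (or
#'   `NULL`), `patients` and `truth`.
#' @export
simulate_cohort <- function(config, vitals = TRUE) {
  stopifnot(inherits(config, "pehr_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  cov <- simulate_covariates(n)
  exposure <- assign_exposure(cov, config)
  surv <- simulate_survival(cov, exposure, config, min_time_days = 26 / 24)

  # ICU length of stay (hours), heavy-tailed like observed ICU stays,
  # floored at 26 h so every subject clears the strict >24 h inclusion.
  los_hours <- pmax(26L, as.integer(round(stats::rlnorm(n, log(3), 1) * 24)))
  # deaths within the cap occur in the ICU: the stay extends (or shortens)
  # to the hour of death and the vitals stream is truncated there
  death_offset_hours <- rep(NA_real_, n)
  died_icu <- surv$event & (surv$time <= config$icu_death_cap_days |
                              surv$time * 24 <= los_hours)
  death_offset_hours[died_icu] <- surv$time[died_icu] * 24
  los_hours[died_icu] <- pmax(26L, ceiling(death_offset_hours[died_icu]))

  baseline <- rtruncnorm(n, config$baseline_hr_mean, config$baseline_hr_sd,
                         55, 95)
  ep_start <- rep(NA_integer_, n)
  ep_end <- rep(NA_real_, n)
  ep_amp <- rep(NA_real_, n)
  died_during <- rep(FALSE, n)
  dr <- config$episode_duration_range
  tr <- config$truncation_run_range
  for (i in which(exposure)) {
    ep_amp[i] <- rtruncnorm(1, config$episode_amplitude_mean,
                            config$episode_amplitude_sd,
                            lower = config$episode_floor - baseline[i])
    if (died_icu[i] &&
        stats::runif(1) < config$death_truncation_prob) {
      # death strikes mid-episode: elevated run of k hours, then death
      k <- sample(seq(tr[1], tr[2]), 1)
      d_hr <- floor(death_offset_hours[i])
      ep_start[i] <- max(1L, d_hr - k)
      ep_end[i] <- death_offset_hours[i]
      died_during[i] <- TRUE
    } else {
      d <- sample(seq(dr[1], dr[2]), 1)
      upper <- if (died_icu[i]) floor(death_offset_hours[i]) else los_hours[i]
      d <- min(d, upper - 2L)
      if (!died_icu[i] && los_hours[i] < d + 3L) los_hours[i] <- d + 3L
      upper <- if (died_icu[i]) floor(death_offset_hours[i]) else los_hours[i]
      ep_start[i] <- sample(seq_len(max(1L, upper - d)), 1)
      ep_end[i] <- ep_start[i] + d
    }
  }

  patients <- cov
  patients$time <- surv$time
  patients$event <- surv$event
  patients$death_offset_hours <- death_offset_hours
  patients$los_hours <- los_hours

  truth <- data.frame(subject_id = cov$subject_id,
                      true_exposure = exposure,
                      episode_start = ep_start,
                      episode_end = ep_end,
                      died_during_episode = died_during)

  vit <- NULL
  if (vitals) {
    parts <- vector("list", n)
    for (i in seq_len(n)) {
      ep <- NULL
      if (exposure[i])
        ep <- data.frame(start = ep_start[i],
                         duration = ep_end[i] - ep_start[i],
                         amplitude = ep_amp[i])
      s <- simulate_hr_series(baseline[i], ep, los_hours[i], config)
      if (died_icu[i])
        s <- s[s$offset_minutes < death_offset_hours[i] * 60, , drop = FALSE]
      if (nrow(s) == 0L)
        s <- data.frame(offset_minutes = 30,
                        heart_rate = baseline[i])
      parts[[i]] <- s
    }
    nrows <- vapply(parts, nrow, integer(1))
    vit <- data.frame(
      subject_id = rep.int(cov$subject_id, nrows),
      offset_minutes = unlist(lapply(parts, `[[`, "offset_minutes"),
                              use.names = FALSE),
      heart_rate = unlist(lapply(parts, `[[`, "heart_rate"),
                          use.names = FALSE)
    )
    vit <- inject_missingness(vit, config$missing_hour_rate)
  }

  # MCAR holes in the lab-like covariates, to exercise screening/imputation
  if (config$covariate_missing_rate > 0) {
    for (nm in c("weight", "map", "temperature", "spo2")) {
      hole <- stats::runif(n) < config$covariate_missing_rate
      patients[[nm]][hole] <- NA_real_
    }
  }

  structure(list(vitals = vit, patients = patients, truth = truth,
                 config = config),
            class = "pehr_cohort")
}

#' @export
print.pehr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d subjects, %s vitals rows\n",
              nrow(x$patients),
              if (is.null(x$vitals)) "no" else format(nrow(x$vitals))))
  cat(sprintf("  true exposure: %d (%.1f%%); deaths by %g d: %d (%.1f%%)\n",
              sum(x$truth$true_exposure),
              100 * mean(x$truth$true_exposure),
              x$config$horizon_days, sum(x$patients$event),
              100 * mean(x$patients$event)))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `vitals.csv` (subject_id, offset_minutes, heart_rate),
#' `patients.csv` and `truth.csv` into `dir`.
#'
#' @param cohort A `pehr_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pehr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$vitals))
    utils::write.csv(cohort$vitals, file.path(dir, "vitals.csv"),
                     row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
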