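test_that("config validation names the offending field", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(episode_prevalence = 1.2, seed = 1),
               "episode_prevalence")
  expect_error(sim_config(n_patients = 0, seed = 1), "n_patients")
  expect_error(sim_config(horizon_days = -1, seed = 1), "horizon_days")
  expect_error(sim_config(episode_duration_range = c(10, 5), seed = 1),
               "episode_duration_range")
  expect_error(sim_config(missing_hour_rate = -0.1, seed = 1),
               "missing_hour_rate")
})

test_that("heart-rate series is deterministic where noise is zero", {
  cfg <- sim_config(measurement_noise_sd = 0, measurement_rate = 4,
                    seed = 1)
  set.seed(11)
  s <- simulate_hr_series(80, NULL, 24, cfg)
  expect_true(all(s$heart_rate == 80))
  expect_true(all(diff(s$offset_minutes) > 0))

  ep <- data.frame(start = 10, duration = 12, amplitude = 30)
  s2 <- simulate_hr_series(80, ep, 30, cfg)
  hr_hour <- s2$offset_minutes %/% 60
  expect_true(all(s2$heart_rate[hr_hour >= 10 & hr_hour < 22] == 110))
  expect_true(all(s2$heart_rate[hr_hour < 10 | hr_hour >= 22] == 80))
})

test_that("overlapping episode intervals are rejected", {
  cfg <- sim_config(seed = 1)
  ep <- data.frame(start = c(5, 10), duration = c(8, 4),
                   amplitude = c(20, 20))
  expect_error(simulate_hr_series(80, ep, 48, cfg), "overlap")
})

test_that("series noise matches the configured distribution", {
  cfg <- sim_config(measurement_noise_sd = 5, measurement_rate = 5,
                    seed = 1)
  set.seed(21)
  s <- simulate_hr_series(80, NULL, 2500, cfg)
  n <- nrow(s)
  expect_gt(n, 10000)
  se <- 5 / sqrt(n)
  expect_lt(abs(mean(s$heart_rate) - 80), 3 * se)
})

test_that("survival generator matches the exponential closed form", {
  # all effects zero, hazard ln(2)/90 -> S(90) = 0.5
  cfg <- sim_config(covariate_effects = c(age = 0),
                    exposure_log_hazard = 0,
                    baseline_hazard = log(2) / 90, seed = 5)
  set.seed(5)
  covs <- data.frame(age = rnorm(5000, 59, 10))
  sv <- simulate_survival(covs, rep(FALSE, 5000), cfg)
  expect_true(all(sv$time <= 90))
  expect_identical(unname(sv$event), unname(sv$time < 90))
  expect_gt(mean(sv$event), 0.48)
  expect_lt(mean(sv$event), 0.52)
})

test_that("zero hazard censors everyone at the horizon", {
  cfg <- sim_config(covariate_effects = c(age = 0), baseline_hazard = 0,
                    seed = 5)
  sv <- simulate_survival(data.frame(age = c(50, 70)), c(TRUE, FALSE), cfg)
  expect_equal(sv$time, c(90, 90))
  expect_false(any(sv$event))
})

test_that("null exposure effect gives indistinguishable survival", {
  cfg <- sim_config(covariate_effects = c(age = 0),
                    exposure_log_hazard = 0,
                    baseline_hazard = log(2) / 90, seed = 5)
  set.seed(99)
  covs <- data.frame(age = rnorm(4000, 59, 10))
  ex <- rep(c(TRUE, FALSE), 2000)
  sv <- simulate_survival(covs, ex, cfg)
  lr <- logrank_test(sv$time, sv$event, ex)
  expect_gt(lr$p, 0.001)
})

test_that("hour-level missingness injection is MCAR at the given rate", {
  set.seed(31)
  samples <- data.frame(subject_id = rep(1:100, each = 100),
                        offset_minutes = rep(seq(30, 99.5 * 60, by = 60),
                                             100),
                        heart_rate = 80)
  expect_identical(inject_missingness(samples, 0), samples)
  expect_equal(nrow(inject_missingness(samples, 1)), 0)
  out <- inject_missingness(samples, 0.1, seed = 7)
  frac <- 1 - nrow(out) / nrow(samples)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
  # reproducible under the seed, and the caller's RNG stream is untouched
  expect_identical(out, inject_missingness(samples, 0.1, seed = 7))
})

test_that("cohorts are reproducible and calibrated to the prevalence", {
  cfg <- sim_config(n_patients = 2000, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$patients, b$patients)
  expect_identical(a$truth, b$truth)
  # injected-exposure fraction within 3-sigma binomial bounds of 0.489
  expect_gt(mean(a$truth$true_exposure), 0.46)
  expect_lt(mean(a$truth$true_exposure), 0.52)
  # every subject clears the >24 h length-of-stay inclusion
  expect_true(all(a$patients$los_hours >= 25))
  expect_true(all(a$patients$time <= 90))
  # death during an episode implies the event and a death hour inside it
  dd <- a$truth$died_during_episode
  expect_true(all(a$patients$event[dd]))
  expect_true(all(a$patients$death_offset_hours[dd] >=
                    a$truth$episode_start[dd]))
  expect_true(all(a$patients$death_offset_hours[dd] <=
                    a$truth$episode_end[dd]))
})

test_that("zero prevalence yields an episode-free cohort", {
  cfg <- sim_config(n_patients = 100, episode_prevalence = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_false(any(co$truth$true_exposure))
  ser <- hourly_medians(co$vitals, setNames(co$patients$los_hours,
                                            co$patients$subject_id))
  calls <- classify_cohort(ser, co$patients, mode = "extended")
  expect_true(all(calls$status == "negative"))
})

test_that("empirical hazard ratio converges to the configured exposure effect", {
  cfg <- sim_config(n_patients = 5000, episode_prevalence = 0.5,
                    covariate_effects = c(age = 0),
                    exposure_coefs = c(age = 0),
                    exposure_log_hazard = log(2),
                    covariate_missing_rate = 0, seed = 17)
  p <- patients_with_truth(cfg)
  fit <- cox_fit(censor_at(p), "exposure")
  expect_lt(abs(fit$table$hr[1] - 2) / 2, 0.10)
})

test_that("cohort tables round-trip through CSV", {
  cfg <- sim_config(n_patients = 30, seed = 9)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- read_vitals(file.path(dir, "vitals.csv"))
  expect_equal(nrow(v), nrow(co$vitals))
  expect_equal(sort(v$heart_rate), sort(co$vitals$heart_rate),
               tolerance = 1e-12)
  p <- read_patients(file.path(dir, "patients.csv"))
  expect_equal(p$time, co$patients$time, tolerance = 1e-12)
  expect_identical(p$event, co$patients$event)
})
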