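test_that("propensity model recovers closed-form and generated truths", {
  # single binary confounder: PS equals the stratum exposure rates
  d <- data.frame(subject_id = 1:200,
                  z = rep(c(1, 0), each = 100),
                  exposure = c(rep(c(TRUE, FALSE), c(70, 30)),
                               rep(c(TRUE, FALSE), c(20, 80))))
  ps <- estimate_propensity(d, covariates = "z")
  expect_equal(sort(unique(round(ps$ps, 10))), c(0.2, 0.7))
  expect_equal(ps$logit_ps, qlogis(ps$ps))

  # null model: PS concentrates at the prevalence
  set.seed(171)
  d2 <- data.frame(subject_id = 1:4000, z = rnorm(4000),
                   exposure = runif(4000) < 0.3)
  ps2 <- estimate_propensity(d2, covariates = "z")
  expect_lt(diff(range(ps2$ps)), 0.15)
  expect_lt(abs(mean(ps2$ps) - mean(d2$exposure)), 0.01)

  # parameter recovery from a known logistic model
  set.seed(181)
  n <- 5000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  eta <- -0.3 + 0.8 * x1 - 0.6 * x2
  d3 <- data.frame(subject_id = 1:n, x1 = x1, x2 = x2,
                   exposure = runif(n) < plogis(eta))
  ps3 <- estimate_propensity(d3, covariates = c("x1", "x2"))
  cf <- attr(ps3, "coef")
  se <- sqrt(diag(vcov(glm(exposure ~ x1 + x2, binomial, d3))))
  expect_true(all(abs(cf - c(-0.3, 0.8, -0.6)) < 3 * se))

  # separation errors out
  d4 <- data.frame(subject_id = 1:40, z = rep(0:1, each = 20),
                   exposure = rep(c(FALSE, TRUE), each = 20))
  expect_error(estimate_propensity(d4, covariates = "z"), "separation")
})

test_that("caliper matching honours the caliper and pairs uniquely", {
  # pairwise-identical PS values: everyone matches at distance 0
  d <- data.frame(subject_id = 1:20,
                  z = rep(seq(-1, 1, length.out = 10), 2),
                  exposure = rep(c(TRUE, FALSE), each = 10))
  ps <- structure(data.frame(subject_id = as.character(1:20),
                             exposure = d$exposure,
                             ps = plogis(rep(seq(-1, 1, length.out = 10), 2)),
                             logit_ps = rep(seq(-1, 1, length.out = 10), 2)),
                  class = c("pehr_ps", "data.frame"))
  m <- nn_match(ps, caliper_sd = 0.2, seed = 3)
  expect_equal(m$n_matched, 10)
  expect_true(all(m$pairs$distance == 0))

  # caliper exclusion: controls at +-0.5 are ineligible under caliper 0.1
  ps2 <- structure(data.frame(
    subject_id = as.character(1:5),
    exposure = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    ps = plogis(c(0, 0.05, -0.05, 0.5, -0.5)),
    logit_ps = c(0, 0.05, -0.05, 0.5, -0.5)),
    class = c("pehr_ps", "data.frame"))
  caliper_sd <- 0.1 / sd(ps2$logit_ps)   # caliper of 0.1 logits
  m2 <- nn_match(ps2, caliper_sd = caliper_sd, seed = 1)
  expect_equal(m2$n_matched, 1)
  expect_true(m2$pairs$control_id %in% c("2", "3"))
  expect_lte(m2$pairs$distance, 0.1)
})

test_that("matching is reproducible and exhaustive with a wide caliper", {
  set.seed(191)
  n <- 400
  lg <- rnorm(n)
  ps <- structure(data.frame(subject_id = as.character(1:n),
                             exposure = rep(c(TRUE, FALSE), each = n / 2),
                             ps = plogis(lg), logit_ps = lg),
                  class = c("pehr_ps", "data.frame"))
  m1 <- nn_match(ps, caliper_sd = 1e6, seed = 5)
  m2 <- nn_match(ps, caliper_sd = 1e6, seed = 5)
  expect_identical(m1$pairs, m2$pairs)
  expect_equal(m1$n_matched, n / 2)   # equal arms, infinite caliper
  expect_false(anyDuplicated(m1$pairs$control_id) > 0)
})

test_that("IPW weights satisfy their identities", {
  set.seed(201)
  n <- 2000
  lg <- rnorm(n, 0, 0.8)
  expz <- runif(n) < plogis(lg)
  ps <- structure(data.frame(subject_id = as.character(1:n),
                             exposure = expz, ps = plogis(lg),
                             logit_ps = lg),
                  class = c("pehr_ps", "data.frame"))
  w <- ipw_weights(ps, stabilized = TRUE)
  expect_true(all(is.finite(w) & w > 0))
  # stabilized weights sum to about the arm size
  expect_lt(abs(sum(w[expz]) / sum(expz) - 1), 0.15)
  expect_lt(abs(sum(w[!expz]) / sum(!expz) - 1), 0.15)
  # no confounding: PS constant at the prevalence -> all weights 1
  ps0 <- ps
  ps0$ps <- mean(expz); ps0$logit_ps <- qlogis(mean(expz))
  expect_equal(ipw_weights(ps0, stabilized = TRUE), rep(1, n),
               tolerance = 1e-12)
})

test_that("SMD formulas match hand computation and identical groups give 0", {
  d <- data.frame(subject_id = 1:200,
                  exposure = rep(c(TRUE, FALSE), each = 100),
                  b = c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60)))
  smd <- smd_table(d, "b")
  expect_equal(unname(smd["b"]), 0.2 / sqrt((0.24 + 0.24) / 2),
               tolerance = 1e-12)
  d2 <- data.frame(subject_id = 1:40,
                   exposure = rep(c(TRUE, FALSE), each = 20),
                   x = rep(rnorm(20), 2), b = rep(rbinom(20, 1, 0.5), 2))
  expect_equal(unname(smd_table(d2, c("x", "b"))), c(0, 0))
  # zero pooled variance with a mean difference is infinite
  d3 <- data.frame(subject_id = 1:10,
                   exposure = rep(c(TRUE, FALSE), each = 5),
                   x = rep(c(1, 2), each = 5))
  expect_equal(unname(smd_table(d3, "x")), Inf)
})

test_that("matching and weighting remove the built-in confounding", {
  cfg <- sim_config(n_patients = 2000, covariate_missing_rate = 0,
                    seed = 211)
  p <- patients_with_truth(cfg)
  ps <- estimate_propensity(p)
  m <- nn_match(ps, seed = 7)
  covs <- c("age", "ventilation", "sofa")
  pre <- smd_table(p, covs)
  post <- smd_table(p, covs, match = m)
  wt <- ipw_weights(ps, stabilized = TRUE)
  wgt <- smd_table(p, covs, weights = wt)
  expect_gt(max(pre), 0.1)
  expect_lt(max(post), 0.1)
  expect_lt(max(wgt), 0.1)
  expect_lte(max(m$pairs$distance), m$caliper)
  # matched KM on a null-effect variant: curves within sampling error
  cfg0 <- sim_config(n_patients = 1500, covariate_missing_rate = 0,
                     exposure_log_hazard = 0, seed = 221)
  p0 <- patients_with_truth(cfg0)
  ps0 <- estimate_propensity(p0)
  m0 <- nn_match(ps0, seed = 7)
  mk <- matched_km(m0, censor_at(p0))
  expect_gt(mk$logrank$p, 0.01)
})

test_that("matched KM reduces confounding bias in the survival contrast", {
  cfg <- sim_config(n_patients = 3000, covariate_missing_rate = 0,
                    seed = 231)
  p <- censor_at(patients_with_truth(cfg))
  grp <- ifelse(p$exposure, "peHR", "no_peHR")
  crude <- km_fit(p$time, p$event, grp)
  ps <- estimate_propensity(p)
  m <- nn_match(ps, seed = 7)
  mk <- matched_km(m, p)
  # the matched contrast must be smaller than the crude (confounded) one
  crude_gap <- survival_at(crude, 89.9, "no_peHR") -
    survival_at(crude, 89.9, "peHR")
  matched_gap <- survival_at(mk$km, 89.9, "no_peHR") -
    survival_at(mk$km, 89.9, "peHR")
  expect_lt(matched_gap, crude_gap)
  expect_gt(matched_gap, 0)
})
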