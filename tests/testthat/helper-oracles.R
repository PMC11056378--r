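# Test-support oracles and fixture builders, independent of the package's
# own computation paths.

# Hand-written Cox partial likelihood for a single covariate with no tied
# event times: risk sets enumerated explicitly, maximized by grid/golden
# section search. Independent of survival::coxph.
cox_pl_oracle <- function(time, event, x) {
  stopifnot(!anyDuplicated(time[event]))
  neg_logpl <- function(beta) {
    val <- 0
    for (i in which(event)) {
      risk <- which(time >= time[i])
      val <- val - (beta * x[i] - log(sum(exp(beta * x[risk]))))
    }
    val
  }
  stats::optimize(neg_logpl, interval = c(-15, 15), tol = 1e-10)$minimum
}

# Random hourly-median series with missing bins, for detector fuzzing.
random_series <- function(span = 72, mean = 100, sd = 12, p_missing = 0.1) {
  bins <- stats::rnorm(span, mean, sd)
  bins[stats::runif(span) < p_missing] <- NA
  bins
}

# Deterministic constructed cohort: n_std subjects with a full qualifying
# window, n_ext subjects whose elevated run is truncated by death, n_neg
# flat-normal subjects. Returns a series set + patient table usable by
# classify_cohort, all with zero noise and zero missingness.
build_fixture_cohort <- function(n_std = 312, n_ext = 52, n_neg = 381) {
  n <- n_std + n_ext + n_neg
  ids <- as.character(seq_len(n))
  kind <- rep(c("std", "ext", "neg"), c(n_std, n_ext, n_neg))
  series <- vector("list", n)
  death <- rep(NA_real_, n)
  los <- rep(48L, n)
  for (i in seq_len(n)) {
    if (kind[i] == "std") {
      bins <- rep(80, 48)
      bins[6:17] <- 110                 # 12 consecutive elevated hours
    } else if (kind[i] == "ext") {
      bins <- rep(80, 30)
      bins[26:30] <- 110                # 5 elevated hours, then death
      death[i] <- 30
      los[i] <- 30L
    } else {
      bins <- rep(80, 48)
    }
    series[[i]] <- list(subject_id = ids[i], bins = bins,
                        span_hours = length(bins),
                        fraction_missing = 0)
  }
  names(series) <- ids
  class(series) <- "pehr_series_set"
  patients <- data.frame(subject_id = ids,
                         time = ifelse(kind == "ext", 30 / 24, 90),
                         event = kind == "ext",
                         death_offset_hours = death,
                         los_hours = los,
                         stringsAsFactors = FALSE)
  list(series = series, patients = patients, kind = kind)
}

# Exposure-confounded patient table without vitals, for survival / PSM
# experiments (true exposure merged in from the ground-truth table).
patients_with_truth <- function(config) {
  co <- simulate_cohort(config, vitals = FALSE)
  p <- co$patients
  p$exposure <- co$truth$true_exposure
  p
}
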