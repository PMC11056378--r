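#' Read a vitals table from CSV
#'
#' Validates the long-format heart-rate table: required columns
#' `subject_id`, `offset_minutes`, `heart_rate`; offsets non-negative;
#' heart rates in the physiological range (0, 300); no duplicated
#' (subject, offset) pair. Malformed rows are reported with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return A validated data frame ordered by subject and offset.
#' @export
read_vitals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "offset_minutes", "heart_rate")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad_rows <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- utils::head(which(cond), 5)
      stop(sprintf("%s in row(s) %s%s", what,
                   paste(rows, collapse = ", "),
                   if (sum(cond, na.rm = TRUE) > 5) " ..." else ""),
           call. = FALSE)
    }
  }
  bad_rows(!is.finite(x$offset_minutes) | x$offset_minutes < 0,
           "invalid offset_minutes")
  bad_rows(!is.finite(x$heart_rate) | x$heart_rate <= 0 |
             x$heart_rate >= 300,
           "heart_rate outside (0, 300)")
  bad_rows(duplicated(x[c("subject_id", "offset_minutes")]),
           "duplicate (subject_id, offset_minutes)")
  x[order(x$subject_id, x$offset_minutes), , drop = FALSE]
}

#' Read a patient covariate/outcome table from CSV
#'
#' @param path CSV file path.
#' @return A validated data frame, one row per subject.
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "event", "los_hours")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$subject_id))
    stop("duplicate subject_id in patient table", call. = FALSE)
  if (any(!is.finite(x$time) | x$time < 0))
    stop("invalid follow-up time", call. = FALSE)
  x$event <- as.logical(x$event)
  x
}

#' Aggregate vitals to per-patient hourly median series
#'
#' Hour bin k is the half-open interval `[60k, 60(k+1))` minutes from each
#' patient's own ICU admission; the bin value is the median of all samples
#' falling in it (even counts average the two central values, the standard
#' [stats::median()] convention) and `NA` when the hour has no samples.
#' The span runs from admission (hour 0) to the last observed hour, or to
#' a per-subject override (e.g. length of stay or hour of death) so that
#' unobserved trailing hours count as missing.
#'
#' @param vitals Data frame with `subject_id`, `offset_minutes`,
#'   `heart_rate`.
#' @param span_hours Optional named vector (names = subject ids) of span
#'   overrides in hours; the span used is the larger of the override and
#'   the last observed hour + 1.
#' @return An object of class `pehr_series_set`: a named list (by subject
#'   id) of lists with `bins` (numeric, `NA` = missing), `span_hours` and
#'   `fraction_missing`.
#' @export
hourly_medians <- function(vitals, span_hours = NULL) {
  stopifnot(all(c("subject_id", "offset_minutes", "heart_rate") %in%
                  names(vitals)))
  if (nrow(vitals) == 0) stop("empty vitals table", call. = FALSE)
  hr_split <- split(vitals[c("offset_minutes", "heart_rate")],
                    vitals$subject_id)
  out <- lapply(names(hr_split), function(id) {
    v <- hr_split[[id]]
    hour <- v$offset_minutes %/% 60
    span <- max(hour) + 1
    if (!is.null(span_hours) && id %in% names(span_hours))
      span <- max(span, span_hours[[id]])
    bins <- rep(NA_real_, span)
    med <- tapply(v$heart_rate, hour, stats::median)
    bins[as.integer(names(med)) + 1L] <- med
    list(subject_id = id, bins = bins, span_hours = as.integer(span),
         fraction_missing = sum(is.na(bins)) / span)
  })
  names(out) <- names(hr_split)
  class(out) <- "pehr_series_set"
  out
}

#' @export
print.pehr_series_set <- function(x, ...) {
  spans <- vapply(x, `[[`, integer(1), "span_hours")
  fm <- vapply(x, `[[`, numeric(1), "fraction_missing")
  cat(sprintf("Hourly heart-rate series: %d subjects; span %d-%d h (median %g); median missing %.1f%%\n",
              length(x), min(spans), max(spans), stats::median(spans),
              100 * stats::median(fm)))
  invisible(x)
}

#' Apply cohort inclusion filters
#'
#' Retains subjects with a length of stay strictly exceeding
#' `los_min_hours` (default 24 h) and at most `max_missing_fraction`
#' (default 20%) missing hourly bins; exclusion requires strictly *more*
#' than the missingness threshold. One reason is logged per excluded
#' subject; rules are checked in order (no vitals, length of stay,
#' missingness) and the first failing rule wins.
#'
#' @param patients Patient table with `subject_id` and `los_hours`.
#' @param series A `pehr_series_set` from [hourly_medians()].
#' @param los_min_hours,max_missing_fraction Thresholds (strict).
#' @return A list with `retained` (subject ids) and `exclusions`
#'   (data frame `subject_id`, `reason`).
#' @export
apply_inclusion_filters <- function(patients, series,
                                    los_min_hours = 24,
                                    max_missing_fraction = 0.20) {
  ids <- as.character(patients$subject_id)
  reason <- rep(NA_character_, length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    if (!id %in% names(series)) {
      reason[j] <- "no vitals"
    } else if (!(patients$los_hours[j] > los_min_hours)) {
      reason[j] <- sprintf("length of stay <= %g h", los_min_hours)
    } else if (series[[id]]$fraction_missing > max_missing_fraction) {
      reason[j] <- sprintf("more than %g%% hourly bins missing",
                           100 * max_missing_fraction)
    }
  }
  excl <- !is.na(reason)
  list(retained = ids[!excl],
       exclusions = data.frame(subject_id = ids[excl],
                               reason = reason[excl],
                               stringsAsFactors = FALSE))
}

#' Screen covariates by missingness
#'
#' Drops covariates whose missing fraction strictly exceeds `threshold`
#' (default 10%); exactly 10% missing is retained. Identifier, outcome and
#' exposure columns are never dropped.
#'
#' @param patients Patient table.
#' @param threshold Maximum tolerated missing fraction.
#' @param protect Column names never dropped.
#' @return Character vector of retained column names.
#' @export
screen_variables <- function(patients, threshold = 0.10,
                             protect = c("subject_id", "time", "event",
                                         "exposure", "death_offset_hours",
                                         "los_hours")) {
  frac <- vapply(patients, function(col) mean(is.na(col)), numeric(1))
  keep <- frac <= threshold | names(patients) %in% protect
  names(patients)[keep]
}

#' Single imputation by predictive mean matching
#'
#' Type-1 PMM with predicted-value distance: for each variable with
#' missing cells, a linear model of that variable on the other numeric
#' covariates is fit on its observed rows; each missing cell is imputed by
#' sampling the observed value of one of the `k_donors` donors whose
#' predicted values lie nearest the recipient's predicted value (all
#' donors tied at the k-th distance are admitted to the pool). Imputed
#' values therefore always lie in the variable's observed support, and
#' observed cells are never altered.
#'
#' @param patients Patient table.
#' @param vars Variables to impute; default every numeric column with
#'   missing values (identifiers/outcomes excluded).
#' @param k_donors Donor pool size (default 5).
#' @param seed Optional seed for a private RNG stream.
#' @return The completed table.
#' @export
pmm_impute <- function(patients, vars = NULL, k_donors = 5, seed = NULL) {
  skip <- c("subject_id", "time", "event", "death_offset_hours",
            "los_hours", "exposure")
  if (is.null(vars)) {
    vars <- names(patients)[vapply(patients, function(col)
      is.numeric(col) && anyNA(col), logical(1))]
    vars <- setdiff(vars, skip)
  }
  if (!length(vars)) return(patients)
  pred_vars <- setdiff(
    names(patients)[vapply(patients, is.numeric, logical(1))],
    c(skip, vars))
  with_seed(seed, {
    for (v in vars) {
      y <- patients[[v]]
      obs <- !is.na(y)
      if (sum(obs) < k_donors)
        stop(sprintf("only %d complete cases for '%s'; use k_donors <= %d",
                     sum(obs), v, sum(obs)), call. = FALSE)
      if (!anyNA(y)) next
      X <- as.matrix(patients[pred_vars])
      # mean-fill predictor holes for prediction purposes only
      for (j in seq_len(ncol(X))) {
        nas <- is.na(X[, j])
        if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
      }
      X <- cbind(1, X)
      fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(X %*% beta)
      pred_obs <- pred[obs]
      y_obs <- y[obs]
      for (i in which(!obs)) {
        d <- abs(pred_obs - pred[i])
        kth <- sort(d, partial = k_donors)[k_donors]
        pool <- which(d <= kth)
        patients[[v]][i] <- y_obs[pool[sample.int(length(pool), 1)]]
      }
    }
    patients
  })
}

#' Average laboratory samples over the first 24 hours
#'
#' Arithmetic mean of each subject's samples with offset strictly below
#' 24 h from admission; subjects with no in-window sample get `NA`.
#'
#' @param samples Data frame with `subject_id`, `offset_minutes` and a
#'   value column.
#' @param value_col Name of the value column.
#' @return Named numeric vector of per-subject first-24-hour means.
#' @export
average_first24h <- function(samples, value_col = "heart_rate") {
  stopifnot(value_col %in% names(samples))
  inside <- samples$offset_minutes < 24 * 60
  ids <- unique(as.character(samples$subject_id))
  out <- rep(NA_real_, length(ids))
  names(out) <- ids
  if (any(inside)) {
    m <- tapply(samples[[value_col]][inside],
                as.character(samples$subject_id)[inside], mean)
    out[names(m)] <- m
  }
  out
}
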