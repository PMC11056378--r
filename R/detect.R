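#' Episode detection rule
#'
#' The standard definition of a prolonged elevated heart rate (peHR)
#' episode: at least `required_hours` hourly median heart rates strictly
#' exceeding `threshold` bpm within any window of `window_hours`
#' consecutive hours (defaults: 11 of 12 h above 100 bpm).
#' `min_terminal_run` parameterises the extended definition: the minimum
#' number of elevated observed hours immediately preceding death.
#'
#' @param threshold Heart-rate threshold, bpm; exceedance is strict (`>`).
#' @param window_hours Window length, hours.
#' @param required_hours Elevated hours required within the window.
#' @param min_terminal_run Extended definition: minimum elevated terminal
#'   run before death.
#' @return A list of class `pehr_rule`.
#' @export
episode_rule <- function(threshold = 100, window_hours = 12L,
                         required_hours = 11L, min_terminal_run = 3L) {
  if (threshold <= 0) stop_field("threshold", "must be > 0")
  if (required_hours < 1 || required_hours > window_hours)
    stop_field("required_hours",
               "must satisfy 1 <= required_hours <= window_hours")
  if (min_terminal_run < 1)
    stop_field("min_terminal_run", "must be >= 1")
  structure(list(threshold = threshold,
                 window_hours = as.integer(window_hours),
                 required_hours = as.integer(required_hours),
                 min_terminal_run = as.integer(min_terminal_run)),
            class = "pehr_rule")
}

#' @export
print.pehr_rule <- function(x, ...) {
  cat(sprintf("peHR rule: >= %d of %d consecutive hourly medians > %g bpm (terminal run >= %d h)\n",
              x$required_hours, x$window_hours, x$threshold,
              x$min_terminal_run))
  invisible(x)
}

# Elevated-bin indicator; missing bins count as non-exceedance (an episode
# is never declared from unobserved hours).
exceed_bins <- function(bins, threshold) {
  !is.na(bins) & bins > threshold
}

#' Detect a standard peHR episode in one hourly series
#'
#' Positive iff some window of `window_hours` consecutive hour bins fully
#' contained in the observed span holds at least `required_hours` bins
#' whose median strictly exceeds the threshold. Missing bins count as
#' non-exceedance. A span shorter than the window is negative (recorded in
#' the call), not an error.
#'
#' @param series One element of a `pehr_series_set` (list with `bins`,
#'   `span_hours`), or a bare numeric vector of hourly medians.
#' @param rule An [episode_rule()].
#' @return A list of class `pehr_call` with `status`
#'   (`"negative"`/`"standard"`), `onset_hour` (0-based start of the
#'   earliest qualifying window, or `NA`) and `qualifying_window_count`.
#' @export
detect_standard <- function(series, rule = episode_rule()) {
  bins <- if (is.list(series)) series$bins else series
  if (!length(bins)) stop("empty series", call. = FALSE)
  span <- length(bins)
  w <- rule$window_hours
  call <- list(subject_id = if (is.list(series)) series$subject_id else NA,
               status = "negative", onset_hour = NA_integer_,
               qualifying_window_count = 0L,
               window_exceeds_span = span < w)
  class(call) <- "pehr_call"
  if (span < w) return(call)
  ex <- exceed_bins(bins, rule$threshold)
  cs <- c(0L, cumsum(ex))
  starts <- seq_len(span - w + 1L)           # 1-based window starts
  counts <- cs[starts + w] - cs[starts]
  hit <- counts >= rule$required_hours
  if (any(hit)) {
    call$status <- "standard"
    call$onset_hour <- which(hit)[1L] - 1L   # 0-based hour index
    call$qualifying_window_count <- sum(hit)
  }
  call
}

#' Brute-force reference detector
#'
#' Exhaustively enumerates every fully contained window and counts
#' elevated bins by direct summation. Deliberately naive: it is the
#' independent reference implementation that [detect_standard()] is
#' validated against.
#'
#' @inheritParams detect_standard
#' @return Same structure as [detect_standard()].
#' @export
detect_standard_oracle <- function(series, rule = episode_rule()) {
  bins <- if (is.list(series)) series$bins else series
  span <- length(bins)
  w <- rule$window_hours
  call <- list(subject_id = if (is.list(series)) series$subject_id else NA,
               status = "negative", onset_hour = NA_integer_,
               qualifying_window_count = 0L,
               window_exceeds_span = span < w)
  class(call) <- "pehr_call"
  if (span < w) return(call)
  for (s in 0:(span - w)) {
    n_elev <- 0L
    for (j in seq_len(w)) {
      b <- bins[s + j]
      if (!is.na(b) && b > rule$threshold) n_elev <- n_elev + 1L
    }
    if (n_elev >= rule$required_hours) {
      if (call$status == "negative") call$onset_hour <- s
      call$status <- "standard"
      call$qualifying_window_count <- call$qualifying_window_count + 1L
    }
  }
  call
}

#' Apply the extended (death-truncated) peHR definition
#'
#' A standard-negative patient who died is reclassified `"extended"` when
#' the final observed hour bins immediately preceding death — at least
#' `min_terminal_run` of them, in an unbroken observed run reaching the
#' last bin (one trailing missing bin tolerated) — all strictly exceed the
#' threshold, i.e. the elevated run was truncated by death before a full
#' qualifying window could complete. Standard status always takes
#' precedence; survivors are never reclassified.
#'
#' @inheritParams detect_standard
#' @param death_hour Hour of death from admission, or `NA`/`NULL` for
#'   survivors (of the ICU stay). Must not exceed the series span.
#' @return A `pehr_call` with status `"negative"`, `"standard"` or
#'   `"extended"`.
#' @export
detect_extended <- function(series, rule = episode_rule(),
                            death_hour = NULL) {
  call <- detect_standard(series, rule)
  if (call$status == "standard") return(call)
  if (is.null(death_hour) || is.na(death_hour)) return(call)
  bins <- if (is.list(series)) series$bins else series
  span <- length(bins)
  if (death_hour > span)
    stop("death_hour exceeds the series span", call. = FALSE)
  last_obs <- max(which(!is.na(bins)), -Inf)
  if (!is.finite(last_obs) || last_obs < span - 1L) return(call)
  run <- 0L
  i <- last_obs
  while (i >= 1L && !is.na(bins[i]) && bins[i] > rule$threshold) {
    run <- run + 1L
    i <- i - 1L
  }
  if (run >= rule$min_terminal_run) call$status <- "extended"
  call
}

#' @export
print.pehr_call <- function(x, ...) {
  cat(sprintf("peHR call: %s (onset %s, %d qualifying window%s)\n",
              x$status,
              if (is.na(x$onset_hour)) "-" else paste0("hour ", x$onset_hour),
              x$qualifying_window_count,
              if (x$qualifying_window_count == 1) "" else "s"))
  invisible(x)
}

#' Classify a whole cohort
#'
#' Runs the detector on every retained subject. In mode `"extended"`
#' (primary analysis) standard-negative decedents are assessed against the
#' extended definition; in mode `"standard_only"` (sensitivity analysis)
#' they remain negative.
#'
#' @param series A `pehr_series_set`.
#' @param patients Patient table; `death_offset_hours` supplies the hour
#'   of in-ICU death (NA otherwise).
#' @param rule An [episode_rule()].
#' @param mode `"extended"` or `"standard_only"`.
#' @return A data frame of class `pehr_calls` with one row per subject
#'   (`subject_id`, `status`, `onset_hour`, `qualifying_window_count`);
#'   attributes `rule`, `mode` and `counts` (n standard, n extended).
#' @export
classify_cohort <- function(series, patients, rule = episode_rule(),
                            mode = c("extended", "standard_only")) {
  mode <- match.arg(mode)
  ids <- as.character(patients$subject_id)
  missing_series <- setdiff(ids, names(series))
  if (length(missing_series))
    stop("no series for subject(s): ",
         paste(utils::head(missing_series, 5), collapse = ", "),
         call. = FALSE)
  death_hour <- if ("death_offset_hours" %in% names(patients))
    patients$death_offset_hours else rep(NA_real_, length(ids))
  calls <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    s <- series[[ids[j]]]
    calls[[j]] <- if (mode == "extended")
      detect_extended(s, rule, death_hour[j])
    else
      detect_standard(s, rule)
  }
  out <- data.frame(
    subject_id = ids,
    status = vapply(calls, `[[`, character(1), "status"),
    onset_hour = vapply(calls, `[[`, integer(1), "onset_hour"),
    qualifying_window_count = vapply(calls, `[[`, integer(1),
                                     "qualifying_window_count"),
    stringsAsFactors = FALSE
  )
  attr(out, "rule") <- rule
  attr(out, "mode") <- mode
  attr(out, "counts") <- c(standard = sum(out$status == "standard"),
                           extended = sum(out$status == "extended"))
  class(out) <- c("pehr_calls", "data.frame")
  out
}

#' @export
print.pehr_calls <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("peHR classification (%s mode): %d subjects; %d standard + %d extended = %d positive (%.1f%%)\n",
              attr(x, "mode"), nrow(x), cnt["standard"], cnt["extended"],
              sum(cnt), 100 * sum(cnt) / nrow(x)))
  print(attr(x, "rule"))
  invisible(x)
}

#' Exposure indicator from a classification table
#'
#' @param calls A `pehr_calls` table.
#' @return Logical vector: status is `"standard"` or `"extended"`.
#' @export
exposure_from_calls <- function(calls) {
  calls$status != "negative"
}
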