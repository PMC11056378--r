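#' Estimate propensity scores
#'
#' Logistic regression of the exposure on the covariates by maximum
#' likelihood. The default covariate set (age, ventilation, SOFA) is the
#' adjustment set identified as most influential for the peHR exposure in
#' the motivating cohort.
#'
#' @param data Data frame with a logical/0-1 exposure column and complete
#'   covariates (impute first).
#' @param covariates Covariate names for the propensity model.
#' @param exposure_col Name of the exposure column.
#' @return A data frame of class `pehr_ps` (`subject_id`, `exposure`,
#'   `ps`, `logit_ps`) with the fitted coefficients as attribute `coef`.
#' @export
estimate_propensity <- function(data,
                                covariates = c("age", "ventilation", "sofa"),
                                exposure_col = "exposure") {
  miss <- setdiff(c(covariates, exposure_col), names(data))
  if (length(miss))
    stop("column(s) absent: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(data[covariates]))
    stop("covariates contain missing values; impute before matching",
         call. = FALSE)
  z <- as.integer(data[[exposure_col]])
  if (!all(z %in% c(0L, 1L)) || length(unique(z)) < 2)
    stop("exposure must be binary with both levels present", call. = FALSE)
  form <- stats::as.formula(paste(
    ".z ~", paste(sprintf("`%s`", covariates), collapse = " + ")))
  dd <- data[covariates]
  dd$.z <- z
  fit <- suppressWarnings(stats::glm(form, data = dd, family = stats::binomial()))
  ps <- stats::fitted(fit)
  eps <- 1e-8
  if (any(ps < eps | ps > 1 - eps))
    stop("propensity scores numerically 0/1 (separation)", call. = FALSE)
  out <- data.frame(subject_id = as.character(data$subject_id),
                    exposure = z == 1L,
                    ps = as.numeric(ps),
                    logit_ps = stats::qlogis(as.numeric(ps)),
                    stringsAsFactors = FALSE)
  attr(out, "coef") <- stats::coef(fit)
  class(out) <- c("pehr_ps", "data.frame")
  out
}

#' 1:1 nearest-neighbour caliper matching on the logit propensity score
#'
#' Greedy matching without replacement: exposed subjects are processed in
#' seeded random order; each is paired with the nearest still-unmatched
#' control by absolute logit-PS distance, provided the distance lies
#' within the caliper. The caliper is `caliper_sd` times the standard
#' deviation of the logit propensity score over all subjects (0.2 by
#' convention).
#'
#' @param ps A `pehr_ps` table from [estimate_propensity()].
#' @param caliper_sd Caliper width as a multiple of SD(logit PS).
#' @param seed Seed for the processing order (private RNG stream).
#' @return An object of class `pehr_match`: `pairs` (data frame
#'   `exposed_id`, `control_id`, `distance`), `caliper`, `n_exposed`,
#'   `n_control`, `n_matched`.
#' @export
nn_match <- function(ps, caliper_sd = 0.2, seed = 1L) {
  stopifnot(inherits(ps, "pehr_ps"))
  exp_ix <- which(ps$exposure)
  ctl_ix <- which(!ps$exposure)
  if (!length(exp_ix) || !length(ctl_ix))
    stop("both arms must be nonempty", call. = FALSE)
  caliper <- caliper_sd * stats::sd(ps$logit_ps)
  lg <- ps$logit_ps
  order_exp <- with_seed(seed, sample(exp_ix))
  available <- rep(TRUE, length(ctl_ix))
  ctl_lg <- lg[ctl_ix]
  pairs <- vector("list", length(order_exp))
  k <- 0L
  for (i in order_exp) {
    d <- abs(ctl_lg - lg[i])
    d[!available] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      available[j] <- FALSE
      k <- k + 1L
      pairs[[k]] <- c(i, ctl_ix[j], d[j])
    }
  }
  pairs <- if (k) do.call(rbind, pairs[seq_len(k)]) else
    matrix(numeric(0), ncol = 3)
  if (k == 0L) stop("no admissible matches within the caliper",
                    call. = FALSE)
  pm <- data.frame(exposed_id = ps$subject_id[pairs[, 1]],
                   control_id = ps$subject_id[pairs[, 2]],
                   distance = pairs[, 3],
                   stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(pm$exposed_id), !anyDuplicated(pm$control_id),
            all(pm$distance <= caliper))
  structure(list(pairs = pm, caliper = caliper,
                 caliper_sd = caliper_sd,
                 n_exposed = length(exp_ix), n_control = length(ctl_ix),
                 n_matched = k),
            class = "pehr_match")
}

#' @export
print.pehr_match <- function(x, ...) {
  cat(sprintf("1:1 caliper matching: %d/%d exposed matched (caliper %.4f = %.2g x SD(logit PS))\n",
              x$n_matched, x$n_exposed, x$caliper, x$caliper_sd))
  invisible(x)
}

#' Inverse probability of treatment weights
#'
#' ATE weights: `1/PS` for exposed, `1/(1-PS)` for controls; the
#' stabilized variant multiplies by the marginal exposure (respectively
#' non-exposure) probability, giving mean weight ~1 per arm.
#'
#' @param ps A `pehr_ps` table.
#' @param stabilized Use stabilized weights.
#' @return Numeric vector of positive, finite weights (one per row of
#'   `ps`).
#' @export
ipw_weights <- function(ps, stabilized = FALSE) {
  stopifnot(inherits(ps, "pehr_ps"))
  eps <- 1e-12
  if (any(ps$ps < eps | ps$ps > 1 - eps))
    stop("propensity scores numerically 0/1; trimming is out of scope",
         call. = FALSE)
  w <- ifelse(ps$exposure, 1 / ps$ps, 1 / (1 - ps$ps))
  if (stabilized) {
    p1 <- mean(ps$exposure)
    w <- w * ifelse(ps$exposure, p1, 1 - p1)
  }
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}

# SMD between two samples (optionally weighted). Binary covariates use the
# proportion-based pooled variance, continuous the mean/variance form;
# zero pooled variance with a nonzero mean difference is infinite.
smd_one <- function(x1, x0, w1 = NULL, w0 = NULL) {
  w1 <- w1 %||% rep(1, length(x1))
  w0 <- w0 %||% rep(1, length(x0))
  binary <- all(stats::na.omit(c(x1, x0)) %in% c(0, 1))
  m1 <- wmean(x1, w1); m0 <- wmean(x0, w0)
  if (binary) {
    v1 <- m1 * (1 - m1); v0 <- m0 * (1 - m0)
  } else {
    v1 <- wvar(x1, w1); v0 <- wvar(x0, w0)
  }
  pooled <- (v1 + v0) / 2
  if (pooled == 0) return(if (m1 == m0) 0 else Inf)
  abs(m1 - m0) / sqrt(pooled)
}

#' Standardized mean differences between exposure groups
#'
#' Computes the absolute SMD per covariate on the crude sample, on the
#' matched sample (given a `pehr_match`) or on the weighted sample (given
#' IPW weights). Continuous covariates use
#' `|m1 - m0| / sqrt((v1 + v0)/2)`; binary covariates use the
#' proportion-based pooled variance.
#'
#' @param data Patient table with `subject_id`, exposure and covariates.
#' @param covariates Covariate names.
#' @param exposure_col Exposure column name.
#' @param match Optional `pehr_match`; restricts to matched subjects.
#' @param weights Optional numeric weights aligned with `data` rows.
#' @return Named numeric vector of absolute SMDs.
#' @export
smd_table <- function(data, covariates, exposure_col = "exposure",
                      match = NULL, weights = NULL) {
  if (!is.null(match) && !is.null(weights))
    stop("give either `match` or `weights`, not both", call. = FALSE)
  z <- as.logical(data[[exposure_col]])
  if (!is.null(match)) {
    keep <- as.character(data$subject_id) %in%
      c(match$pairs$exposed_id, match$pairs$control_id)
    data <- data[keep, , drop = FALSE]
    z <- z[keep]
    weights <- NULL
  }
  vapply(covariates, function(v) {
    x <- as.numeric(data[[v]])
    smd_one(x[z], x[!z],
            if (!is.null(weights)) weights[z],
            if (!is.null(weights)) weights[!z])
  }, numeric(1))
}

#' Kaplan-Meier and log-rank analysis on the matched sample
#'
#' @param match A `pehr_match`.
#' @param data Patient table with `subject_id`, `time`, `event`.
#' @return A list with `km` (a `pehr_km` with groups `"peHR"` /
#'   `"no_peHR"`), `logrank` (a `pehr_logrank`) and `n`.
#' @export
matched_km <- function(match, data) {
  stopifnot(inherits(match, "pehr_match"))
  ids <- as.character(data$subject_id)
  sel_e <- ids %in% match$pairs$exposed_id
  sel_c <- ids %in% match$pairs$control_id
  keep <- sel_e | sel_c
  if (!any(keep)) stop("no matched subjects found in data", call. = FALSE)
  grp <- ifelse(sel_e[keep], "peHR", "no_peHR")
  list(km = km_fit(data$time[keep], data$event[keep], grp),
       logrank = logrank_test(data$time[keep], data$event[keep], grp),
       n = sum(keep))
}
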