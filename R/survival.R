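#' Administrative censoring at a fixed horizon
#'
#' Follow-up is truncated at `horizon` days: later times are set to the
#' horizon and their events to censored.
#'
#' @param data Data frame with `time` and `event` columns.
#' @param horizon Horizon in days (default 90).
#' @return `data` with censored `time`/`event`.
#' @export
censor_at <- function(data, horizon = 90) {
  over <- data$time > horizon
  data$event[over] <- FALSE
  data$time[over] <- horizon
  data
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with Greenwood variance, computed by
#' [survival::survfit()]. Ties at an event time are processed together and
#' subjects censored at t remain at risk for events at t (the standard
#' convention).
#'
#' @param time Follow-up times (> 0), days.
#' @param event Logical event indicators.
#' @param group Optional group labels; `NULL` fits a single curve.
#' @return An object of class `pehr_km`: a named list of per-group curves,
#'   each a data frame `time`, `n_risk`, `n_event`, `surv`, `var`
#'   (Greenwood variance of the survival estimate).
#' @export
km_fit <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  if (any(table(group) == 0) || length(time) == 0)
    stop("empty group", call. = FALSE)
  event <- as.integer(event)
  df <- data.frame(time = time, event = event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(unique(group), length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  curves <- lapply(split(seq_along(sm$time), strata), function(ix) {
    data.frame(time = sm$time[ix],
               n_risk = sm$n.risk[ix],
               n_event = sm$n.event[ix],
               surv = sm$surv[ix],
               var = sm$std.err[ix]^2)
  })
  structure(curves, class = "pehr_km")
}

#' @export
print.pehr_km <- function(x, ...) {
  cat("Kaplan-Meier fit\n")
  for (g in names(x)) {
    cur <- x[[g]]
    cat(sprintf("  %s: n=%d, %d events, S(last=%g) = %.3f\n",
                g, max(cur$n_risk), sum(cur$n_event),
                max(cur$time), cur$surv[nrow(cur)]))
  }
  invisible(x)
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of the Kaplan-Meier curve: at a
#' step time the post-step value is returned. A query beyond the last
#' observed time returns the last value with a warning.
#'
#' @param fit A `pehr_km` object.
#' @param t Time in days (>= 0).
#' @param group Group name; defaults to the first (only) curve.
#' @return Survival probability.
#' @export
survival_at <- function(fit, t, group = NULL) {
  stopifnot(inherits(fit, "pehr_km"), t >= 0)
  cur <- fit[[group %||% 1L]]
  if (is.null(cur)) stop("unknown group", call. = FALSE)
  if (t > max(cur$time))
    warning("time beyond last observation; returning last value")
  idx <- findInterval(t, cur$time)   # right-continuous: step at t included
  if (idx == 0) 1 else cur$surv[idx]
}

#' Log-rank test
#'
#' Standard log-rank chi-square with (groups - 1) degrees of freedom,
#' computed by [survival::survdiff()].
#'
#' @param time,event,group As in [km_fit()]; at least two nonempty groups.
#' @return A list of class `pehr_logrank`: `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  tab <- table(group)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab == 0)) stop("empty group", call. = FALSE)
  df0 <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df0)
  k <- length(tab) - 1L
  structure(list(statistic = unname(sd$chisq), df = k,
                 p = stats::pchisq(sd$chisq, k, lower.tail = FALSE)),
            class = "pehr_logrank")
}

#' @export
print.pehr_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood via [survival::coxph()] (Efron tie
#' handling by default, Breslow by flag) and reports per-covariate hazard
#' ratios with Wald 95% confidence intervals and Wald p-values, matching
#' the HR / 95% CI / p presentation conventional in clinical tables.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names (numeric
#'   or 0/1 after encoding; no constant column).
#' @param ties `"efron"` or `"breslow"`.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `pehr_cox`: `table` (term, coef, se, hr,
#'   ci_low, ci_high, p), `loglik`, `n`, `n_event`, `ties`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("covariate(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dd <- data[c("time", "event", covariates)]
  dd$event <- as.integer(dd$event)
  for (v in covariates) {
    x <- dd[[v]]
    if (is.logical(x)) dd[[v]] <- as.integer(x)
    x <- dd[[v]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) < 2)
      stop("constant covariate: ", v, call. = FALSE)
  }
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = dd, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w),
             " (possible separation; penalization is out of scope)",
             call. = FALSE)
      suppressWarnings(
        survival::coxph(form, data = dd, ties = ties,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100)))
    })
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("singular information matrix in Cox fit", call. = FALSE)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = covariates,
                    coef = unname(beta),
                    se = se,
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 loglik = fit$loglik[2],
                 n = fit$n, n_event = fit$nevent,
                 ties = ties, conf_level = conf_level),
            class = "pehr_cox")
}

#' @export
print.pehr_cox <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  tab <- x$table
  out <- data.frame(term = tab$term,
                    HR = round(tab$hr, digits),
                    CI = sprintf("%.*f-%.*f", digits, tab$ci_low,
                                 digits, tab$ci_high),
                    p = signif(tab$p, 2))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pehr_cox <- function(object, ...) {
  stats::setNames(object$table$coef, object$table$term)
}

#' @export
summary.pehr_cox <- function(object, ...) {
  object$table
}
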