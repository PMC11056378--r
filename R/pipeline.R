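#' Baseline-table group comparisons
#'
#' Summarizes each variable per exposure group and tests for a group
#' difference: continuous variables are shown as median (IQR) and tested
#' by t-test (default) or Wilcoxon rank-sum; categorical variables as
#' n (%) and tested by chi-square. For 2x2 tables the continuity-corrected
#' chi-square is the default (the variant that reproduces the published
#' baseline-table p-values); larger tables use the uncorrected Pearson
#' statistic; any table with an expected cell count below 1 is routed to
#' Fisher's exact test. The test used is recorded per row.
#'
#' @param data Patient table.
#' @param group_col Name of the (binary or categorical) grouping column.
#' @param vars Variables to summarize; default every column except
#'   identifiers/outcomes and the grouping variable.
#' @param continuous_test `"t"` or `"wilcox"`.
#' @return A data frame of class `pehr_table1`: `variable`, one summary
#'   column per group, `test`, `p`.
#' @export
compare_groups <- function(data, group_col = "exposure", vars = NULL,
                           continuous_test = c("t", "wilcox")) {
  continuous_test <- match.arg(continuous_test)
  if (!group_col %in% names(data))
    stop("grouping column absent: ", group_col, call. = FALSE)
  g <- data[[group_col]]
  if (is.logical(g)) g <- ifelse(g, "peHR", "no_peHR")
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(vars))
    vars <- setdiff(names(data),
                    c("subject_id", "time", "event", "death_offset_hours",
                      group_col))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("variable(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)

  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    is_cat <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && all(stats::na.omit(x) %in% c(0, 1)))
    if (!is_cat) {
      sm <- vapply(levels(g), function(lv) {
        q <- stats::quantile(x[g == lv], c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
      }, character(1))
      tst <- if (continuous_test == "t") {
        if (nlevels(g) == 2)
          list(name = "t", p = stats::t.test(x ~ g)$p.value)
        else
          list(name = "ANOVA",
               p = summary(stats::aov(x ~ g))[[1]][["Pr(>F)"]][1])
      } else {
        list(name = "rank-sum", p = stats::wilcox.test(x ~ g)$p.value)
      }
    } else {
      xv <- if (is.numeric(x)) factor(x, levels = c(0, 1)) else factor(x)
      tab <- table(xv, g)
      lvl_show <- if (nlevels(xv) == 2) nlevels(xv) else seq_len(nlevels(xv))
      sm <- vapply(levels(g), function(lv) {
        n1 <- sum(tab[lvl_show, lv])
        sprintf("%d (%.0f%%)", n1, 100 * n1 / sum(tab[, lv]))
      }, character(1))
      tst <- categorical_test(tab)
    }
    out <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (lv in levels(g)) out[[lv]] <- sm[[lv]]
    out$test <- tst$name
    out$p <- tst$p
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pehr_table1", "data.frame")
  out
}

# Routing rule for categorical tests; see compare_groups().
categorical_test <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2)
    return(list(name = "none (constant)", p = NA_real_))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    return(list(name = "Fisher",
                p = stats::fisher.test(tab)$p.value))
  if (nrow(tab) == 2 && ncol(tab) == 2)
    return(list(name = "corrected chi-square",
                p = suppressWarnings(
                  stats::chisq.test(tab, correct = TRUE)$p.value)))
  list(name = "chi-square",
       p = suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value))
}

#' @export
print.pehr_table1 <- function(x, ...) {
  y <- x
  y$p <- signif(y$p, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Run the full peHR analysis pipeline
#'
#' Executes, in fixed order: cohort simulation (or CSV ingest), hourly
#' median aggregation, inclusion filtering, variable screening and PMM
#' imputation, episode classification (extended mode plus the
#' standard-only sensitivity rerun), baseline-table group comparison,
#' crude Kaplan-Meier with log-rank, univariable and multivariable Cox
#' models, propensity-score matching with balance diagnostics and matched
#' Kaplan-Meier, inverse-probability weighting, and the
#' threshold-by-duration hazard-ratio grid. All outputs are written as CSV
#' into `out_dir` together with a JSON run manifest; the run is a pure
#' function of (config, seed).
#'
#' @param config A [pipeline_config()] whose `sim` component defines the
#'   synthetic cohort, or `vitals`/`patients` supplied directly.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param seed Overrides `config$sim$seed`.
#' @param vitals,patients Optional pre-loaded input tables (bypass
#'   simulation); both must be given together.
#' @return An object of class `pehr_run` bundling every stage result.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL, vitals = NULL, patients = NULL) {
  stopifnot(inherits(config, "pehr_config"))
  t0 <- Sys.time()
  log_counts <- list()

  # -- stage: data source ---------------------------------------------------
  truth <- NULL
  if (is.null(vitals) != is.null(patients))
    stop("supply both `vitals` and `patients`, or neither", call. = FALSE)
  if (is.null(vitals)) {
    if (is.null(config$sim))
      stop("config$sim is required when no input tables are given",
           call. = FALSE)
    sim <- config$sim
    if (!is.null(seed)) {
      sim$seed <- as.integer(seed)
    }
    cohort <- simulate_cohort(sim)
    vitals <- cohort$vitals
    patients <- cohort$patients
    truth <- cohort$truth
  }
  log_counts$n_input <- nrow(patients)

  # -- stage: ingest --------------------------------------------------------
  series <- hourly_medians(
    vitals, stats::setNames(patients$los_hours,
                            as.character(patients$subject_id)))
  filt <- apply_inclusion_filters(patients, series,
                                  los_min_hours = config$los_min_hours,
                                  max_missing_fraction =
                                    config$max_missing_fraction)
  retained <- patients[as.character(patients$subject_id) %in%
                         filt$retained, , drop = FALSE]
  series <- series[as.character(retained$subject_id)]
  class(series) <- "pehr_series_set"
  log_counts$n_retained <- nrow(retained)
  log_counts$n_excluded <- nrow(filt$exclusions)
  stopifnot(log_counts$n_input ==
              log_counts$n_retained + log_counts$n_excluded)

  # -- stage: screen + impute ----------------------------------------------
  kept_vars <- screen_variables(retained,
                                threshold = config$var_missing_threshold)
  dropped_vars <- setdiff(names(retained), kept_vars)
  retained <- retained[kept_vars]
  retained <- pmm_impute(retained, k_donors = config$k_donors,
                         seed = config$sim$seed %||% 1L)

  # -- stage: detect --------------------------------------------------------
  rule <- episode_rule(threshold = config$hr_threshold,
                       window_hours = config$window_hours,
                       required_hours = config$required_hours,
                       min_terminal_run = config$min_terminal_run)
  calls <- classify_cohort(series, retained, rule, mode = "extended")
  calls_std <- classify_cohort(series, retained, rule,
                               mode = "standard_only")
  retained$exposure <- exposure_from_calls(calls)
  log_counts$n_standard <- unname(attr(calls, "counts")["standard"])
  log_counts$n_extended <- unname(attr(calls, "counts")["extended"])

  # -- stage: describe ------------------------------------------------------
  analysis <- censor_at(retained, config$horizon_days)
  table1 <- compare_groups(analysis,
                           vars = setdiff(names(analysis),
                                          c("subject_id", "time", "event",
                                            "death_offset_hours",
                                            "los_hours", "exposure")),
                           continuous_test = config$continuous_test)

  # -- stage: survive -------------------------------------------------------
  grp <- ifelse(analysis$exposure, "peHR", "no_peHR")
  km <- km_fit(analysis$time, analysis$event, grp)
  lr <- logrank_test(analysis$time, analysis$event, grp)
  surv90 <- vapply(c("peHR", "no_peHR"), function(g)
    survival_at(km, config$horizon_days - 1e-9, g), numeric(1))
  cox_uni <- cox_fit(analysis, "exposure")
  cox_multi <- cox_fit(analysis, c("exposure", config$cox_covariates))

  analysis_std <- analysis
  analysis_std$exposure <- exposure_from_calls(calls_std)
  cox_sens <- cox_fit(analysis_std, c("exposure", config$cox_covariates))

  # -- stage: match ---------------------------------------------------------
  ps <- estimate_propensity(analysis, config$psm_covariates)
  match <- nn_match(ps, caliper_sd = config$caliper_sd,
                    seed = config$sim$seed %||% 1L)
  w <- ipw_weights(ps, stabilized = TRUE)
  smd <- data.frame(
    covariate = config$psm_covariates,
    crude = smd_table(analysis, config$psm_covariates),
    matched = smd_table(analysis, config$psm_covariates, match = match),
    weighted = smd_table(analysis, config$psm_covariates, weights = w),
    stringsAsFactors = FALSE)
  mkm <- matched_km(match, analysis)
  msurv90 <- vapply(c("peHR", "no_peHR"), function(g)
    survival_at(mkm$km, config$horizon_days - 1e-9, g), numeric(1))

  # -- stage: grid ----------------------------------------------------------
  grid <- run_grid(series, analysis,
                   thresholds = config$grid_thresholds,
                   durations = config$grid_durations,
                   adjust_covariates = config$grid_covariates,
                   min_terminal_run = config$min_terminal_run)
  grid_violations <- check_monotonicity(grid)

  res <- structure(list(
    config = config,
    truth = truth,
    exclusions = filt$exclusions,
    dropped_variables = dropped_vars,
    patients = analysis,
    series = series,
    calls = calls,
    calls_standard_only = calls_std,
    table1 = table1,
    km = km, logrank = lr, surv90 = surv90,
    cox_univariate = cox_uni,
    cox_multivariate = cox_multi,
    cox_sensitivity = cox_sens,
    ps = ps, match = match, smd = smd,
    matched_km = mkm, matched_surv90 = msurv90,
    grid = grid, grid_violations = grid_violations,
    counts = log_counts
  ), class = "pehr_run")

  if (!is.null(out_dir)) write_run(res, out_dir, t0)
  res
}

# Serialize a pipeline run: one CSV per stage output + JSON manifest.
write_run <- function(res, out_dir, t0 = Sys.time()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    path
  }
  km_df <- function(km) do.call(rbind, lapply(names(km), function(g)
    cbind(group = g, km[[g]])))
  files <- c(
    wr(res$exclusions, "exclusions.csv"),
    wr(as.data.frame(res$calls), "episode_calls.csv"),
    wr(as.data.frame(res$table1), "table1.csv"),
    wr(km_df(res$km), "km_curves.csv"),
    wr(res$cox_univariate$table, "cox_univariate.csv"),
    wr(res$cox_multivariate$table, "cox_multivariate.csv"),
    wr(res$cox_sensitivity$table, "cox_sensitivity_standard_only.csv"),
    wr(res$match$pairs, "matched_pairs.csv"),
    wr(res$smd, "smd.csv"),
    wr(km_df(res$matched_km$km), "km_curves_matched.csv"),
    wr(as.data.frame(res$grid), "grid.csv")
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("pehr")),
    seed = res$config$sim$seed,
    config = list(hr_threshold = res$config$hr_threshold,
                  window_hours = res$config$window_hours,
                  required_hours = res$config$required_hours,
                  min_terminal_run = res$config$min_terminal_run,
                  caliper_sd = res$config$caliper_sd,
                  horizon_days = res$config$horizon_days),
    counts = res$counts,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(md5 = unname(tools::md5sum(f)), rows = nrow(utils::read.csv(f)))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pehr_run <- function(x, ...) {
  cat("peHR pipeline run\n")
  cat(sprintf("  cohort: %d in, %d retained, %d excluded\n",
              x$counts$n_input, x$counts$n_retained, x$counts$n_excluded))
  cat(sprintf("  peHR: %d standard + %d extended = %d of %d (%.1f%%)\n",
              x$counts$n_standard, x$counts$n_extended,
              x$counts$n_standard + x$counts$n_extended,
              x$counts$n_retained,
              100 * (x$counts$n_standard + x$counts$n_extended) /
                x$counts$n_retained))
  cat(sprintf("  90-day survival: %.1f%% (no peHR) vs %.1f%% (peHR); log-rank p = %.3g\n",
              100 * x$surv90["no_peHR"], 100 * x$surv90["peHR"],
              x$logrank$p))
  uni <- x$cox_univariate$table[1, ]
  mul <- x$cox_multivariate$table[x$cox_multivariate$table$term ==
                                    "exposure", ]
  cat(sprintf("  crude HR %.2f (%.2f-%.2f); adjusted HR %.2f (%.2f-%.2f)\n",
              uni$hr, uni$ci_low, uni$ci_high,
              mul$hr, mul$ci_low, mul$ci_high))
  cat(sprintf("  matched: %d pairs, max post-match SMD %.3f; matched survival %.1f%% vs %.1f%%\n",
              x$match$n_matched, max(x$smd$matched),
              100 * x$matched_surv90["no_peHR"],
              100 * x$matched_surv90["peHR"]))
  cat(sprintf("  grid: %d cells, %d monotonicity violations\n",
              nrow(x$grid), nrow(x$grid_violations)))
  invisible(x)
}

#' @export
summary.pehr_run <- function(object, ...) {
  list(counts = object$counts,
       surv90 = object$surv90,
       matched_surv90 = object$matched_surv90,
       crude_hr = object$cox_univariate$table$hr[1],
       adjusted_hr = object$cox_multivariate$table$hr[
         object$cox_multivariate$table$term == "exposure"],
       logrank_p = object$logrank$p,
       smd = object$smd)
}
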