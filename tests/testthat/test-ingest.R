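test_that("vitals reader validates structure and ranges", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "v.csv")
  ok <- data.frame(subject_id = c(1, 1, 2),
                   offset_minutes = c(0, 30, 10),
                   heart_rate = c(80, 90, 100))
  write.csv(ok, f, row.names = FALSE)
  expect_equal(nrow(read_vitals(f)), 3)

  bad <- ok
  bad$heart_rate[2] <- -5
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_vitals(f), "row\\(s\\) 2")

  dup <- ok
  dup$offset_minutes[2] <- 0
  write.csv(dup, f, row.names = FALSE)
  expect_error(read_vitals(f), "duplicate")

  write.csv(ok[c("subject_id", "heart_rate")], f, row.names = FALSE)
  expect_error(read_vitals(f), "offset_minutes")
})

test_that("hourly medians follow the stated bin conventions", {
  v <- data.frame(subject_id = 1,
                  offset_minutes = c(10, 20, 50, 70, 80),
                  heart_rate = c(90, 100, 110, 90, 110))
  s <- hourly_medians(v)[["1"]]
  expect_equal(s$bins, c(100, 100))     # odd count, then even-count mean
  expect_equal(s$span_hours, 2)
  expect_equal(s$fraction_missing, 0)

  # empty bins are missing; span override extends the denominator
  v2 <- data.frame(subject_id = 1, offset_minutes = c(30, 150),
                   heart_rate = c(80, 90))
  s2 <- hourly_medians(v2)[["1"]]
  expect_equal(s2$bins, c(80, NA, 90))
  expect_equal(s2$fraction_missing, 1 / 3)
  s3 <- hourly_medians(v2, c("1" = 5))[["1"]]
  expect_equal(s3$span_hours, 5)
  expect_equal(s3$fraction_missing, 3 / 5)
})

test_that("hourly binning is order-invariant and matches a sort-based oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- 200
    v <- data.frame(subject_id = sample(1:5, n, replace = TRUE),
                    offset_minutes = runif(n, 0, 50 * 60),
                    heart_rate = runif(n, 60, 140))
    v <- v[!duplicated(v[c("subject_id", "offset_minutes")]), ]
    s1 <- hourly_medians(v)
    s2 <- hourly_medians(v[sample(nrow(v)), ])
    expect_identical(s1, s2)
    # independent oracle: filter-then-sort median per (subject, hour)
    for (id in unique(v$subject_id)) {
      vi <- v[v$subject_id == id, ]
      bins <- s1[[as.character(id)]]$bins
      for (k in seq_along(bins)) {
        inwin <- vi$heart_rate[vi$offset_minutes >= (k - 1) * 60 &
                                 vi$offset_minutes < k * 60]
        if (!length(inwin)) {
          expect_true(is.na(bins[k]))
        } else {
          srt <- sort(inwin)
          m <- length(srt)
          med <- if (m %% 2) srt[(m + 1) / 2] else
            (srt[m / 2] + srt[m / 2 + 1]) / 2
          expect_equal(bins[k], med)
        }
      }
    }
  }
})

test_that("inclusion filters use strict boundaries", {
  mk_series <- function(id, span, n_missing) {
    bins <- rep(80, span)
    if (n_missing) bins[seq_len(n_missing)] <- NA
    list(subject_id = id, bins = bins, span_hours = span,
         fraction_missing = n_missing / span)
  }
  series <- list("1" = mk_series("1", 100, 21),  # 21% missing -> excluded
                 "2" = mk_series("2", 100, 20),  # exactly 20% -> retained
                 "3" = mk_series("3", 48, 0),
                 "4" = mk_series("4", 48, 0))
  class(series) <- "pehr_series_set"
  patients <- data.frame(subject_id = as.character(1:5),
                         los_hours = c(100, 100, 24, 25, 48),
                         stringsAsFactors = FALSE)
  res <- apply_inclusion_filters(patients, series)
  expect_setequal(res$retained, c("2", "4"))
  reasons <- setNames(res$exclusions$reason, res$exclusions$subject_id)
  expect_match(reasons[["1"]], "missing")
  expect_match(reasons[["3"]], "length of stay")  # exactly 24 h is excluded
  expect_match(reasons[["5"]], "no vitals")
})

test_that("variable screening drops strictly above 10% missing", {
  n <- 100
  tab <- data.frame(subject_id = 1:n, time = 90, event = FALSE,
                    los_hours = 48,
                    a = c(rep(NA, 11), rnorm(n - 11)),   # 11% -> dropped
                    b = c(rep(NA, 10), rnorm(n - 10)),   # 10% -> retained
                    c = rnorm(n))
  kept <- screen_variables(tab)
  expect_false("a" %in% kept)
  expect_true(all(c("b", "c") %in% kept))
  # no missingness anywhere: everything retained
  expect_setequal(screen_variables(tab[c("subject_id", "time", "event",
                                         "los_hours", "c")]),
                  c("subject_id", "time", "event", "los_hours", "c"))
})

test_that("PMM imputes from the observed support and respects observed cells", {
  set.seed(51)
  n <- 400
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, 0, 0.5)
  tab <- data.frame(subject_id = 1:n, time = 90, event = FALSE,
                    los_hours = 48, x = x, y = y)
  tab$y[sample(n, 40)] <- NA
  out <- pmm_impute(tab, seed = 1)
  expect_false(anyNA(out$y))
  obs <- !is.na(tab$y)
  expect_identical(out$y[obs], tab$y[obs])
  expect_identical(out$x, tab$x)
  expect_true(all(out$y[!obs] %in% tab$y[obs]))
  # zero-missing table is returned unchanged
  expect_identical(pmm_impute(out, seed = 1), out)
  # donor-pool size guard
  small <- tab[1:6, ]
  small$y[1:3] <- NA
  expect_error(pmm_impute(small, k_donors = 5), "k_donors")
})

test_that("PMM recovers the pre-deletion mean under MCAR", {
  set.seed(61)
  n <- 1000
  x <- rnorm(n)
  y <- 1 + 3 * x + rnorm(n)
  tab <- data.frame(subject_id = 1:n, time = 90, event = FALSE,
                    los_hours = 48, x = x, y = y)
  full_mean <- mean(y)
  tab$y[sample(n, 80)] <- NA          # 8% MCAR
  out <- pmm_impute(tab, seed = 2)
  se <- sd(y) / sqrt(n)
  expect_lt(abs(mean(out$y) - full_mean), 3 * se)
})

test_that("first-24h averaging windows strictly and matches brute force", {
  s <- data.frame(subject_id = c(1, 1, 1, 2, 3),
                  offset_minutes = c(60, 120, 25 * 60, 30 * 60, 100),
                  heart_rate = c(10, 20, 999, 50, 7))
  out <- average_first24h(s)
  expect_equal(unname(out[["1"]]), 15)
  expect_true(is.na(out[["2"]]))      # only out-of-window samples
  expect_equal(unname(out[["3"]]), 7)
  set.seed(71)
  big <- data.frame(subject_id = sample(1:20, 500, TRUE),
                    offset_minutes = runif(500, 0, 72 * 60),
                    heart_rate = rnorm(500, 80, 10))
  got <- average_first24h(big)
  for (id in unique(big$subject_id)) {
    v <- big[big$subject_id == id & big$offset_minutes < 1440, ]
    want <- if (nrow(v)) mean(v$heart_rate) else NA_real_
    expect_equal(unname(got[[as.character(id)]]), want)
  }
})
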