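test_that("the feature universe has exactly 28 canonical members", {
  fid <- feature_ids()
  expect_equal(nrow(fid), 28)
  expect_equal(anyDuplicated(fid$name), 0)
  # window 1 admits only the mean
  expect_true(all(fid$aggregate[fid$window == 1] == "mean"))
  # 4 quantities x (1 + 3 + 3) combinations
  expect_equal(as.vector(table(fid$quantity)), rep(7L, 4))
})

test_that("lagged aggregates use only the prior days, with stated arithmetic", {
  rec <- make_records("P01", 4, seed = 3,
    steps = c(1000, 2000, 3000, 99999))
  cases <- build_cases(rec)
  expect_equal(nrow(cases), 1) # only day 4 has three observed prior days
  expect_equal(cases$date, rec$date[4])
  expect_equal(sum(names(cases) %in% feature_ids()$name), 28)
  expect_equal(cases$steps_mean_3d, 2000)
  expect_equal(cases$steps_min_3d, 1000)
  expect_equal(cases$steps_max_3d, 3000)
  expect_equal(cases$steps_mean_1d, 3000) # day d itself (99999) never enters
  expect_equal(cases$steps_mean_2d, 2500)
  expect_equal(cases$light_sleep_s, rec$light_sleep_s[4])

  expect_equal(nrow(build_cases(make_records("P02", 3, seed = 4))), 0)
})

test_that("case emission matches a brute-force day-by-day completeness check", {
  set.seed(77)
  for (rep in 1:5) {
    rec <- make_records(sprintf("P%02d", rep), 60)
    # 20% missingness scattered over measurement cells
    for (col in setdiff(names(rec), c("participant_id", "date"))) {
      rec[[col]][runif(60) < 0.2] <- NA
    }
    # also drop whole rows, which must count as all-missing days
    rec <- rec[runif(60) > 0.1, ]
    cases <- build_cases(rec)

    act <- c("steps", "light_activity_s", "moderate_activity_s",
      "intense_activity_s")
    days <- seq(min(rec$date), max(rec$date), by = "day")
    expected <- 0
    for (d in days[-(1:3)]) {
      row_d <- rec[rec$date == d, ]
      sleep_ok <- nrow(row_d) == 1 && !is.na(row_d$light_sleep_s) &&
        !is.na(row_d$deep_sleep_s)
      act_ok <- all(vapply(1:3, function(k) {
        r <- rec[rec$date == d - k, ]
        nrow(r) == 1 && !anyNA(r[, act])
      }, logical(1)))
      expected <- expected + (sleep_ok && act_ok)
    }
    expect_equal(nrow(cases), expected)
    if (nrow(cases) > 0) expect_false(anyNA(cases))
  }
})

test_that("build_cases is shift-equivariant in steps and order-invariant", {
  rec <- make_records("P01", 20, seed = 11)
  base <- build_cases(rec)
  shifted <- rec
  shifted$steps <- shifted$steps + 500
  out <- build_cases(shifted)
  step_cols <- grep("^steps_", names(base), value = TRUE)
  dur_cols <- setdiff(grep("_\\dd$", names(base), value = TRUE), step_cols)
  for (col in step_cols) expect_equal(out[[col]], base[[col]] + 500)
  for (col in dur_cols) expect_equal(out[[col]], base[[col]])
  expect_equal(out$light_sleep_s, base$light_sleep_s)

  scrambled <- rec[sample(nrow(rec)), ]
  expect_equal(build_cases(scrambled), base)
})

test_that("inclusion requires strictly more than min_days cases", {
  # 33 fully observed days yield exactly 30 cases; 34 yield 31
  r30 <- make_records("P30", 33, seed = 21)
  r31 <- make_records("P31", 34, seed = 22)
  r10 <- make_records("P10", 13, seed = 23)
  cases <- build_cases(dplyr::bind_rows(r30, r31, r10))
  expect_equal(as.vector(table(cases$participant_id)[c("P30", "P31")]),
    c(30L, 31L))
  filt <- eligibility_filter(cases, min_days = 30)
  expect_setequal(unique(filt$included$participant_id), "P31")
  expect_setequal(filt$excluded, c("P30", "P10"))

  empty <- eligibility_filter(cases[0, ])
  expect_equal(nrow(empty$included), 0)
  expect_length(empty$excluded, 0)
})

test_that("per-participant standardization gives mean 0, SD 1 per column", {
  rec <- dplyr::bind_rows(
    make_records("P01", 25, seed = 31),
    make_records("P02", 25, seed = 32)
  )
  cases <- build_cases(rec)
  std <- standardize_per_participant(cases)
  value_cols <- setdiff(names(std), c("participant_id", "date"))
  for (pid in unique(std$participant_id)) {
    sub <- std[std$participant_id == pid, ]
    for (col in value_cols) {
      expect_lt(abs(mean(sub[[col]])), 1e-10)
      expect_equal(sd(sub[[col]]), 1, tolerance = 1e-12)
    }
  }
  # sample SD convention: {2, 4} -> -1/sqrt(2), +1/sqrt(2)
  two <- cases[cases$participant_id == "P01", ][1:2, ]
  two$light_sleep_s <- c(2, 4)
  std2 <- suppressWarnings(standardize_per_participant(two))
  expect_equal(std2$light_sleep_s, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("columns constant within any participant are excluded and reported", {
  rec <- dplyr::bind_rows(
    make_records("P01", 20, seed = 41),
    make_records("P02", 20, seed = 42)
  )
  rec$intense_activity_s[rec$participant_id == "P01"] <- 600
  cases <- build_cases(rec)
  expect_warning(std <- standardize_per_participant(cases),
    "intense_activity")
  excl <- attr(std, "excluded_features")
  expect_true(all(grepl("^intense_activity_", excl)))
  expect_equal(length(excl), 7) # all windows/aggregates of that quantity
  expect_false(any(excl %in% names(std)))
})
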