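#' The universe of lagged activity features
#'
#' Each feature is an aggregate (mean, minimum or maximum) of one activity
#' quantity (step count or the duration of light, moderate or intense
#' activity) over a window of the 1, 2 or 3 days preceding the sleep day.
#' For a one-day window mean, minimum and maximum coincide, so only the
#' mean is kept; with the default windows this yields
#' 4 quantities x (1 + 3 + 3) = 28 distinct features.
#'
#' @param windows Integer vector of window lengths in days (default 1:3).
#' @return A tibble with columns `quantity`, `aggregate`, `window` and
#'   `name`, one row per feature. Names follow the pattern
#'   `<quantity>_<aggregate>_<w>d`, e.g. `"steps_min_3d"`.
#' @examples
#' nrow(feature_ids()) # 28
#' @export
feature_ids <- function(windows = 1:3) {
  windows <- sort(unique(as.integer(windows)))
  stopifnot(length(windows) >= 1, all(windows >= 1))
  grid <- expand.grid(
    aggregate = c("mean", "min", "max"),
    window = windows,
    quantity = names(activity_quantities),
    stringsAsFactors = FALSE
  )
  # one-day windows: min/max duplicate the mean; keep the canonical mean form
  grid <- grid[!(grid$window == 1 & grid$aggregate != "mean"), ]
  tibble::tibble(
    quantity = grid$quantity,
    aggregate = grid$aggregate,
    window = grid$window,
    name = sprintf("%s_%s_%dd", grid$quantity, grid$aggregate, grid$window)
  )
}

# Matrix of lagged copies of v: column k holds v shifted down by k days
# (value for day i is v[i - k], NA for the first k days).
lag_matrix <- function(v, w) {
  n <- length(v)
  vapply(seq_len(w), function(k) c(rep(NA_real_, k), v)[seq_len(n)], numeric(n))
}

# Aggregate the first `w` lag columns row-wise.
aggregate_lags <- function(lags, w, aggregate) {
  m <- lags[, seq_len(w), drop = FALSE]
  switch(aggregate,
    mean = rowMeans(m),
    min  = do.call(pmin, c(as.data.frame(m), na.rm = FALSE)),
    max  = do.call(pmax, c(as.data.frame(m), na.rm = FALSE)),
    stop("unknown aggregate: ", aggregate)
  )
}

#' Build the case table of sleep targets and lagged activity features
#'
#' A case is one analyzable participant-day: the light and deep sleep
#' durations recorded on day d together with the lagged aggregate features
#' of activity on days d-1 ... d-3. A day becomes a case only if both sleep
#' targets are present on day d and all four activity quantities are present
#' on every one of the `max(windows)` preceding calendar days, so that every
#' emitted case carries the complete feature set with no missing values.
#' Lags are calendar-day lags: a missing day (absent row or missing cells)
#' breaks the window.
#'
#' @param records Daily records as returned by [read_daily_records()] or
#'   [generate_cohort()].
#' @param windows Window lengths in days; default `1:3`.
#' @return A tibble (`case table`) with `participant_id`, `date`, one column
#'   per feature (see [feature_ids()]) and the two targets `light_sleep_s`,
#'   `deep_sleep_s`. Insufficient data yields an empty table, not an error.
#' @export
build_cases <- function(records, windows = 1:3) {
  fid <- feature_ids(windows)
  W <- max(fid$window)
  empty <- tibble::tibble(
    participant_id = character(), date = as.Date(character())
  )
  for (nm in fid$name) empty[[nm]] <- numeric()
  empty$light_sleep_s <- numeric()
  empty$deep_sleep_s <- numeric()
  if (nrow(records) == 0) return(empty)

  per_participant <- lapply(
    split(records, records$participant_id),
    function(df) {
      df <- df[order(df$date), ]
      days <- seq(min(df$date), max(df$date), by = "day")
      n <- length(days)
      if (n < W + 1) return(NULL)
      idx <- match(days, df$date) # NA where the calendar day has no row
      A <- vapply(activity_quantities,
        function(col) as.numeric(df[[col]][idx]), numeric(n))
      ls <- as.numeric(df$light_sleep_s[idx])
      ds <- as.numeric(df$deep_sleep_s[idx])

      activity_complete <- rowSums(is.na(A)) == 0
      d <- (W + 1):n
      ok <- !is.na(ls[d]) & !is.na(ds[d])
      for (k in seq_len(W)) ok <- ok & activity_complete[d - k]
      d <- d[ok]
      if (length(d) == 0) return(NULL)

      lags <- lapply(seq_len(ncol(A)), function(q) lag_matrix(A[, q], W))
      feats <- matrix(NA_real_, length(d), nrow(fid),
        dimnames = list(NULL, fid$name))
      for (i in seq_len(nrow(fid))) {
        q <- match(fid$quantity[i], names(activity_quantities))
        full <- aggregate_lags(lags[[q]], fid$window[i], fid$aggregate[i])
        feats[, i] <- full[d]
      }
      out <- tibble::tibble(
        participant_id = df$participant_id[1],
        date = days[d]
      )
      out <- dplyr::bind_cols(out, tibble::as_tibble(feats))
      out$light_sleep_s <- ls[d]
      out$deep_sleep_s <- ds[d]
      out
    }
  )
  res <- dplyr::bind_rows(per_participant)
  if (nrow(res) == 0) empty else res
}

#' Participant inclusion filter
#'
#' Retains participants contributing strictly more than `min_days` complete
#' cases (the "> 30 days of data" inclusion rule); all others are listed as
#' excluded.
#'
#' @param case_table A case table from [build_cases()].
#' @param min_days Threshold; a participant is included iff their case count
#'   exceeds it strictly. Default 30.
#' @return A list with `included` (the filtered case table) and `excluded`
#'   (character vector of excluded participant ids).
#' @export
eligibility_filter <- function(case_table, min_days = 30) {
  counts <- table(case_table$participant_id)
  keep <- names(counts)[counts > min_days]
  list(
    included = case_table[case_table$participant_id %in% keep, , drop = FALSE],
    excluded = sort(setdiff(names(counts), keep))
  )
}

#' Per-participant z-standardization for pooled analysis
#'
#' Standardizes every feature and both sleep targets within each participant
#' (subtract the participant mean, divide by the participant sample SD,
#' n - 1 denominator) so that pooled group-level analyses are not dominated
#' by between-person differences in average activity and sleep. A column
#' that is constant within any participant carries no rank or subgroup
#' information for that participant and would pool z-scores of mixed
#' meaning, so it is dropped from the output for all participants and
#' reported via a warning and the `"excluded_features"` attribute.
#'
#' @param case_table A case table; every participant needs at least 2 cases.
#' @return The standardized case table (constant columns removed), with
#'   attribute `excluded_features`.
#' @export
standardize_per_participant <- function(case_table) {
  value_cols <- setdiff(names(case_table), c("participant_id", "date"))
  groups <- split(seq_len(nrow(case_table)), case_table$participant_id)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every participant needs at least 2 cases to standardize")
  }
  excluded <- character()
  out <- case_table
  for (col in value_cols) {
    v <- as.numeric(case_table[[col]])
    for (ix in groups) {
      s <- stats::sd(v[ix])
      if (!is.finite(s) || s == 0) {
        excluded <- union(excluded, col)
        break
      }
      out[[col]] <- replace(out[[col]], ix, (v[ix] - mean(v[ix])) / s)
    }
  }
  if (length(excluded) > 0) {
    warning("constant within-participant column(s) excluded from pooled analysis: ",
      paste(excluded, collapse = ", "))
    out <- out[, setdiff(names(out), excluded), drop = FALSE]
  }
  attr(out, "excluded_features") <- excluded
  out
}
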