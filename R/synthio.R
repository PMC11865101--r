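#' Read daily tracker records from CSV
#'
#' Expects the exact schema header
#' `participant_id,date,steps,light_activity_s,moderate_activity_s,intense_activity_s,light_sleep_s,deep_sleep_s`
#' with ISO 8601 dates and empty cells for missing measurements. Records are
#' validated (non-negative counts, durations in `[0, 86400)`, unique
#' participant/date keys) and returned sorted by participant and date.
#'
#' @param source Path or connection to a CSV file.
#' @return A tibble of daily records.
#' @export
read_daily_records <- function(source) {
  rec <- readr::read_csv(
    source,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      date = readr::col_date(format = "%Y-%m-%d"),
      .default = readr::col_double()
    ),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
  if (!identical(names(rec), daily_record_columns)) {
    stop("schema error: header must be exactly: ",
      paste(daily_record_columns, collapse = ","))
  }
  validate_daily_records(rec)
  rec[order(rec$participant_id, rec$date), ]
}

validate_daily_records <- function(rec) {
  if (anyNA(rec$participant_id) || anyNA(rec$date)) {
    stop("schema error: participant_id and date must be present and parseable")
  }
  key <- paste(rec$participant_id, rec$date, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    stop("schema error: duplicate (participant_id, date): ",
      paste(unique(dup), collapse = ", "))
  }
  measure_cols <- setdiff(daily_record_columns, c("participant_id", "date"))
  for (col in measure_cols) {
    v <- rec[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop(sprintf("validation error: negative %s at row %d", col, bad[1]))
    }
  }
  for (col in setdiff(measure_cols, "steps")) {
    v <- rec[[col]]
    bad <- which(!is.na(v) & v >= SECONDS_PER_DAY)
    if (length(bad) > 0) {
      stop(sprintf(
        "validation error: %s of %.0f s at row %d is not a valid daily duration",
        col, v[bad[1]], bad[1]))
    }
  }
  invisible(rec)
}

#' Write daily tracker records to CSV
#'
#' Inverse of [read_daily_records()]: missing measurements become empty
#' cells and `read_daily_records(write_daily_records(x))` reproduces `x`
#' field for field. Output is byte-stable for identical input.
#'
#' @param records Tibble of daily records satisfying the schema invariants.
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_daily_records <- function(records, path) {
  stopifnot(identical(names(records), daily_record_columns))
  validate_daily_records(records)
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Configuration of a synthetic tracker cohort
#'
#' Describes a cohort of participants with heterogeneous habitual activity
#' and sleep. Participant-level means are drawn once per participant
#' (log-normal for steps and activity durations, normal for sleep), then
#' daily values are drawn around them: log-normal steps, gamma activity
#' durations (right-skewed, as tracker activity data are), normal sleep
#' clamped at 0 and rounded to whole seconds. Default location parameters
#' follow a cohort with median ~4000 steps/day (between-person medians
#' spanning roughly 1000-10000), ~3 h light activity, ~20-min moderate and
#' intense bouts, and ~7.5 h total sleep split into light and deep
#' components. Missingness is independent per measurement cell per day
#' (MCAR).
#'
#' @param n_participants Number of participants.
#' @param days_per_participant Scalar, or vector of length `n_participants`,
#'   of consecutive monitored days each.
#' @param steps_median,steps_between_sdlog Median of participant-level mean
#'   daily steps, and log-scale SD of those means across participants.
#' @param steps_cv Within-participant coefficient of variation of daily steps.
#' @param light_activity_mean_s,moderate_activity_mean_s,intense_activity_mean_s
#'   Cohort medians of participant-level mean daily durations (seconds).
#' @param activity_between_sdlog Log-scale SD of participant-level activity
#'   means.
#' @param activity_shape Gamma shape of daily activity durations.
#' @param light_sleep_mean_s,deep_sleep_mean_s Cohort means of
#'   participant-level mean daily sleep durations (seconds).
#' @param sleep_between_sd_s SD of participant-level sleep means (seconds).
#' @param sleep_within_sd_s Within-participant daily SD of each sleep
#'   duration (seconds); also the unit of planted-effect shifts.
#' @param missingness Probability that any one measurement cell is missing.
#' @param seed Default random seed for [generate_cohort()].
#' @param planted_effects List of [planted_effect()] objects.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 18,
                          days_per_participant = 200,
                          steps_median = 4000,
                          steps_between_sdlog = 0.7,
                          steps_cv = 0.5,
                          light_activity_mean_s = 11040,
                          moderate_activity_mean_s = 1140,
                          intense_activity_mean_s = 1320,
                          activity_between_sdlog = 0.45,
                          activity_shape = 3,
                          light_sleep_mean_s = 13500,
                          deep_sleep_mean_s = 13380,
                          sleep_between_sd_s = 1800,
                          sleep_within_sd_s = 2700,
                          missingness = 0.08,
                          seed = 1L,
                          planted_effects = list()) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    days_per_participant = as.integer(days_per_participant),
    steps_median = steps_median,
    steps_between_sdlog = steps_between_sdlog,
    steps_cv = steps_cv,
    light_activity_mean_s = light_activity_mean_s,
    moderate_activity_mean_s = moderate_activity_mean_s,
    intense_activity_mean_s = intense_activity_mean_s,
    activity_between_sdlog = activity_between_sdlog,
    activity_shape = activity_shape,
    light_sleep_mean_s = light_sleep_mean_s,
    deep_sleep_mean_s = deep_sleep_mean_s,
    sleep_between_sd_s = sleep_between_sd_s,
    sleep_within_sd_s = sleep_within_sd_s,
    missingness = missingness,
    seed = as.integer(seed),
    planted_effects = planted_effects
  )
  stopifnot(
    cfg$n_participants >= 0,
    all(cfg$days_per_participant >= 0),
    length(cfg$days_per_participant) %in% c(1L, max(1L, cfg$n_participants)),
    cfg$steps_between_sdlog >= 0, cfg$steps_cv >= 0,
    cfg$activity_between_sdlog >= 0, cfg$activity_shape > 0,
    cfg$sleep_between_sd_s >= 0, cfg$sleep_within_sd_s >= 0,
    cfg$missingness >= 0, cfg$missingness <= 1
  )
  for (pe in cfg$planted_effects) {
    if (!inherits(pe, "planted_effect")) {
      stop("planted_effects must be a list of planted_effect() objects")
    }
  }
  structure(cfg, class = "cohort_config")
}

#' A planted lagged activity-to-sleep effect
#'
#' Ground truth for recovery experiments: after a participant's activity
#' series is simulated, the chosen lagged feature is computed day by day, a
#' threshold is placed at the given quantile of its marginal, and the sleep
#' target mean on qualifying days is shifted by `shift` within-participant
#' target SDs. This is a step-function effect, matching the threshold
#' conditions the subgroup search looks for.
#'
#' @param target `"light_sleep"` or `"deep_sleep"`.
#' @param feature A feature name from [feature_ids()], e.g. `"steps_min_3d"`.
#' @param operator `"<="` or `">="`; which side of the threshold qualifies.
#' @param quantile Quantile in (0, 1) of the feature's marginal at which the
#'   threshold sits. The implied subgroup fraction (`quantile` for `<=`,
#'   `1 - quantile` for `>=`) must lie in (0.10, 0.90).
#' @param shift Mean shift on qualifying days, in units of the participant's
#'   within-person target SD.
#' @param participants Character vector of participant ids to affect, or
#'   `NULL` for all.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(target = c("light_sleep", "deep_sleep"),
                           feature, operator = c("<=", ">="),
                           quantile, shift, participants = NULL) {
  target <- match.arg(target)
  operator <- match.arg(operator)
  fid <- feature_ids()
  if (!feature %in% fid$name) {
    stop("unknown feature: ", feature)
  }
  stopifnot(quantile > 0, quantile < 1, is.numeric(shift))
  implied <- if (operator == "<=") quantile else 1 - quantile
  if (implied <= 0.10 || implied >= 0.90) {
    stop("configuration error: planted subgroup fraction ",
      signif(implied, 3), " outside (0.10, 0.90)")
  }
  structure(
    list(target = target, feature = feature, operator = operator,
      quantile = quantile, shift = shift, participants = participants),
    class = "planted_effect"
  )
}

# Feature values (one per day, NA for the first `window` days) of one lagged
# aggregate, computed from the complete simulated activity matrix.
planted_descriptor_values <- function(A, feature) {
  fid <- feature_ids()
  row <- fid[fid$name == feature, ]
  q <- match(row$quantity, names(activity_quantities))
  lags <- lag_matrix(A[, q], row$window)
  aggregate_lags(lags, row$window, row$aggregate)
}

#' Generate a synthetic tracker cohort
#'
#' Simulates daily records for each participant on consecutive calendar
#' days according to a [cohort_config()]: activity first, then sleep, then
#' any planted effects (threshold on a lagged activity feature, mean shift
#' of the target on qualifying days), then MCAR missingness. Identical
#' config and seed give identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Random seed; defaults to the seed stored in `config`.
#' @return A tibble of daily records in the [read_daily_records()] schema.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  empty <- tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    steps = numeric(), light_activity_s = numeric(),
    moderate_activity_s = numeric(), intense_activity_s = numeric(),
    light_sleep_s = numeric(), deep_sleep_s = numeric()
  )
  if (config$n_participants == 0) return(empty)
  ndays <- rep_len(config$days_per_participant, config$n_participants)
  start <- as.Date("2021-01-01")
  out <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", i)
    nd <- ndays[i]
    if (nd == 0) next

    # participant-level habitual means
    steps_mu <- stats::rlnorm(1, log(config$steps_median),
      config$steps_between_sdlog)
    act_mu <- vapply(
      c(config$light_activity_mean_s, config$moderate_activity_mean_s,
        config$intense_activity_mean_s),
      function(m) stats::rlnorm(1, log(m), config$activity_between_sdlog),
      numeric(1))
    sleep_mu <- pmax(1800, stats::rnorm(2,
      c(config$light_sleep_mean_s, config$deep_sleep_mean_s),
      config$sleep_between_sd_s))

    # daily activity: log-normal steps with mean steps_mu, gamma durations
    sdlog <- sqrt(log(1 + config$steps_cv^2))
    steps <- round(stats::rlnorm(nd, log(steps_mu) - sdlog^2 / 2, sdlog))
    durations <- vapply(act_mu, function(m) {
      pmin(stats::rgamma(nd, shape = config$activity_shape,
        rate = config$activity_shape / m), SECONDS_PER_DAY - 1)
    }, numeric(nd))
    if (nd == 1) durations <- matrix(durations, nrow = 1)
    A <- cbind(steps, durations)

    light_sleep <- stats::rnorm(nd, sleep_mu[1], config$sleep_within_sd_s)
    deep_sleep <- stats::rnorm(nd, sleep_mu[2], config$sleep_within_sd_s)

    for (pe in config$planted_effects) {
      if (!is.null(pe$participants) && !pid %in% pe$participants) next
      desc <- planted_descriptor_values(A, pe$feature)
      defined <- which(!is.na(desc))
      if (length(defined) == 0) next
      thr <- stats::quantile(desc[defined], pe$quantile, names = FALSE)
      qual <- if (pe$operator == "<=") {
        defined[desc[defined] <= thr]
      } else {
        defined[desc[defined] >= thr]
      }
      frac <- length(qual) / length(defined)
      if (frac <= 0.10 || frac >= 0.90) {
        stop("configuration error: realized planted subgroup fraction ",
          signif(frac, 3), " outside (0.10, 0.90) for ", pe$feature)
      }
      delta <- pe$shift * config$sleep_within_sd_s
      if (pe$target == "light_sleep") {
        light_sleep[qual] <- light_sleep[qual] + delta
      } else {
        deep_sleep[qual] <- deep_sleep[qual] + delta
      }
    }

    rec <- tibble::tibble(
      participant_id = pid,
      date = start + 0:(nd - 1),
      steps = steps,
      light_activity_s = round(A[, 2]),
      moderate_activity_s = round(A[, 3]),
      intense_activity_s = round(A[, 4]),
      light_sleep_s = round(pmin(pmax(light_sleep, 0), SECONDS_PER_DAY - 1)),
      deep_sleep_s = round(pmin(pmax(deep_sleep, 0), SECONDS_PER_DAY - 1))
    )
    if (config$missingness > 0) {
      for (col in setdiff(daily_record_columns, c("participant_id", "date"))) {
        drop <- stats::runif(nd) < config$missingness
        rec[[col]][drop] <- NA_real_
      }
    }
    out[[i]] <- rec
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty else res
}
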