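#' Render a subgroup condition as study-report text
#'
#' Deterministic template mirroring the reporting style of the analysis
#' tables: "minimum number of steps in prior 3 days ≤ 779", "duration
#' of moderate physical activities previous day ≥ 62 min". Step
#' thresholds print as integers; duration thresholds in minutes, or hours
#' and minutes from two hours up. Standardized (group-level) thresholds are
#' unit-less and print in SD units. The 28 feature phrases are pairwise
#' distinct, so the rendering identifies the condition uniquely.
#'
#' @param condition A list or one-row data frame with `feature`, `operator`
#'   (`"<="`/`">="`) and `threshold`.
#' @param standardized Set `TRUE` for thresholds on standardized data.
#' @return A single string.
#' @export
render_condition_text <- function(condition, standardized = FALSE) {
  fid <- feature_ids()
  row <- fid[fid$name == condition$feature, ]
  if (nrow(row) != 1) stop("unknown feature: ", condition$feature)
  agg_word <- c(mean = "average", min = "minimum", max = "maximum")[row$aggregate]
  level <- sub("_activity", "", row$quantity)
  phrase <- if (row$quantity == "steps") {
    if (row$window == 1) {
      "number of steps previous day"
    } else {
      sprintf("%s number of steps in prior %d days", agg_word, row$window)
    }
  } else {
    if (row$window == 1) {
      sprintf("duration of %s physical activities previous day", level)
    } else {
      sprintf("%s duration of %s physical activities in prior %d days",
        agg_word, level, row$window)
    }
  }
  op <- c("<=" = "≤", ">=" = "≥")[condition$operator]
  value <- if (standardized) {
    sprintf("%.2f SD", condition$threshold)
  } else if (row$quantity == "steps") {
    format(round(condition$threshold), scientific = FALSE, trim = TRUE)
  } else {
    mins <- round(condition$threshold / 60)
    if (mins < 120) {
      sprintf("%d min", mins)
    } else {
      sprintf("%d h and %d min", mins %/% 60, mins %% 60)
    }
  }
  paste(phrase, op, value)
}

#' Configuration of a full study run
#'
#' Bundles the input (a daily-record CSV path or a [cohort_config()]) with
#' every analysis setting: inclusion threshold, lag windows, significance
#' level, subgroup-size bounds, permutation count and seeds, and which
#' analysis modes to run.
#'
#' @param input Path to a daily-record CSV, or a [cohort_config()].
#' @param min_days Inclusion threshold (strictly more cases than this).
#' @param windows Lag windows in days.
#' @param alpha Significance level for both the Holm screen and the
#'   permutation test.
#' @param min_frac,max_frac Subgroup-size bounds.
#' @param n_permutations Permutations per subgroup test.
#' @param seed_generation Seed for synthetic-cohort generation.
#' @param seed_permutation Base seed for permutation streams; per-scope
#'   seeds are derived from it deterministically.
#' @param modes Analysis modes to run: `"individual"`, `"group"` or both.
#' @param permute_group Permutation scheme in group mode (`"within"`
#'   participant by default, or `"global"`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, min_days = 30, windows = 1:3, alpha = 0.05,
                       min_frac = 0.10, max_frac = 0.90,
                       n_permutations = 1000, seed_generation = 1L,
                       seed_permutation = 2L,
                       modes = c("individual", "group"),
                       permute_group = c("within", "global")) {
  modes <- match.arg(modes, several.ok = TRUE)
  permute_group <- match.arg(permute_group)
  stopifnot(
    min_frac > 0, min_frac < max_frac, max_frac < 1,
    alpha > 0, alpha < 1, min_days >= 0, n_permutations >= 100
  )
  structure(list(
    input = input, min_days = min_days, windows = windows, alpha = alpha,
    min_frac = min_frac, max_frac = max_frac,
    n_permutations = n_permutations,
    seed_generation = as.integer(seed_generation),
    seed_permutation = as.integer(seed_permutation),
    modes = modes, permute_group = permute_group
  ), class = "run_config")
}

# Deterministic per-(scope, target) permutation seed, kept inside the
# 32-bit integer range.
derive_seed <- function(base, scope_index, target_index) {
  as.integer((base + 7919 * scope_index + 104729 * target_index) %%
    (.Machine$integer.max - 1) + 1)
}

#' Run the complete activity-sleep study replica
#'
#' End to end: ingest or generate daily records, build the case table,
#' apply the inclusion filter, screen Spearman correlations under Holm
#' control, search the best subgroup per scope and target, and validate it
#' with the swap-randomization permutation test — per participant
#' (`"individual"` mode) and on the pooled per-participant-standardized
#' table (`"group"` mode). Only subgroups that satisfy the size bounds and
#' whose permutation p-value is below `alpha` enter the significant-results
#' table (asserted on every run). Output is a pure function of the config
#' and seeds, so reports are byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `correlations.csv`, `subgroups.csv`, `dfd.json` and `log.txt`.
#' @return A list of class `study_report`: `counts`, `correlations`,
#'   `headline_correlations`, `subgroups` (best per scope and target, with
#'   p-values and condition text), `significant_subgroups`, `dfd` (per-test
#'   summaries), `excluded_participants`, `excluded_features`, `provenance`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  records <- if (inherits(config$input, "cohort_config")) {
    generate_cohort(config$input, seed = config$seed_generation)
  } else {
    read_daily_records(config$input)
  }
  n_total <- length(unique(records$participant_id))
  note("records: %d rows, %d participants", nrow(records), n_total)

  cases <- build_cases(records, windows = config$windows)
  filt <- eligibility_filter(cases, min_days = config$min_days)
  included <- filt$included
  ids <- sort(unique(included$participant_id))
  # participants with no complete case at all are excluded too
  excluded_ids <- sort(setdiff(unique(records$participant_id), ids))
  note("cases: %d complete; included participants: %d of %d (> %d cases)",
    nrow(cases), length(ids), n_total, config$min_days)

  correlations <- NULL
  subgroup_rows <- NULL
  dfd_summaries <- list()
  excluded_features <- character()
  targets <- unname(sleep_targets)

  analyze_scope <- function(tab, scope, scope_index, standardized) {
    rows <- NULL
    for (tj in seq_along(targets)) {
      tg <- targets[tj]
      if (!tg %in% names(tab)) next
      res <- dfd_test(tab, target = tg,
        n_permutations = config$n_permutations,
        seed = derive_seed(config$seed_permutation, scope_index, tj),
        alpha = config$alpha, min_frac = config$min_frac,
        max_frac = config$max_frac,
        permute = if (standardized) config$permute_group else "global")
      if (nrow(res$best) == 0) next
      row <- res$best
      row$scope <- scope
      row$p_value <- res$p_value
      row$significant <- res$significant
      row$condition_text <- render_condition_text(
        list(feature = row$feature, operator = row$operator,
          threshold = row$threshold),
        standardized = standardized)
      rows <- dplyr::bind_rows(rows, row)
      dfd_summaries[[paste(scope, tg, sep = "/")]] <<- list(
        scope = scope, target = tg,
        observed_quality = res$observed_quality,
        n_permutations = res$n_permutations, p_value = res$p_value,
        significant = res$significant, seed = res$seed,
        permute = res$permute,
        null_quality_mean = mean(res$null_qualities),
        null_quality_q95 = unname(quantile(res$null_qualities, 0.95))
      )
    }
    rows
  }

  if ("individual" %in% config$modes && length(ids) > 0) {
    correlations <- run_correlation_screen(included, mode = "individual",
      alpha = config$alpha)
    for (si in seq_along(ids)) {
      tab <- included[included$participant_id == ids[si], , drop = FALSE]
      if (nrow(tab) < 10) next
      subgroup_rows <- dplyr::bind_rows(subgroup_rows,
        analyze_scope(tab, ids[si], si, standardized = FALSE))
    }
    note("individual mode: %d scopes, %d correlation tests",
      length(ids), sum(correlations$scope != "GROUP"))
  }

  if ("group" %in% config$modes && length(ids) > 0) {
    std <- withCallingHandlers(
      standardize_per_participant(included),
      warning = function(w) {
        note("group mode: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    excluded_features <- attr(std, "excluded_features")
    group_cor <- run_correlation_screen(std, mode = "group",
      alpha = config$alpha)
    correlations <- dplyr::bind_rows(correlations, group_cor)
    if (nrow(std) >= 10) {
      subgroup_rows <- dplyr::bind_rows(subgroup_rows,
        analyze_scope(std, "GROUP", length(ids) + 1L, standardized = TRUE))
    }
    note("group mode: %d pooled cases, %d columns excluded as constant",
      nrow(std), length(excluded_features))
  }

  significant <- if (!is.null(subgroup_rows)) {
    subgroup_rows[subgroup_rows$significant, , drop = FALSE]
  } else {
    NULL
  }
  # gatekeeping invariant: nothing outside the size bounds or above alpha
  if (!is.null(significant) && nrow(significant) > 0) {
    stopifnot(
      all(significant$size_frac >= config$min_frac),
      all(significant$size_frac <= config$max_frac),
      all(significant$p_value < config$alpha)
    )
  }

  sig_ids <- unique(c(
    if (!is.null(significant)) setdiff(significant$scope, "GROUP"),
    if (!is.null(correlations)) {
      correlations$scope[correlations$holm_reject &
        correlations$scope != "GROUP"]
    }
  ))
  counts <- list(
    participants_total = n_total,
    participants_included = length(ids),
    participants_with_significant_finding = length(sig_ids),
    cases_total = nrow(cases),
    cases_included = nrow(included)
  )
  note("findings: %d participants with at least one significant result",
    counts$participants_with_significant_finding)

  headline <- if (!is.null(correlations)) {
    correlations[correlations$headline, , drop = FALSE]
  } else {
    NULL
  }
  report <- structure(list(
    counts = counts,
    correlations = correlations,
    headline_correlations = headline,
    subgroups = subgroup_rows,
    significant_subgroups = significant,
    dfd = dfd_summaries,
    excluded_participants = excluded_ids,
    excluded_features = excluded_features,
    provenance = list(
      config = unclass(config[setdiff(names(config), "input")]),
      input = if (inherits(config$input, "cohort_config")) {
        unclass(config$input)
      } else {
        as.character(config$input)
      },
      package_version = as.character(utils::packageVersion("actisleep"))
    ),
    log = log_lines
  ), class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

# Persist the report: JSON summary, CSV tables, permutation summaries, log.
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_report <- report[c("counts", "headline_correlations",
    "significant_subgroups", "excluded_participants", "excluded_features",
    "provenance")]
  jsonlite::write_json(json_report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  if (!is.null(report$correlations)) {
    readr::write_csv(report$correlations,
      file.path(out_dir, "correlations.csv"), progress = FALSE)
  }
  if (!is.null(report$subgroups)) {
    readr::write_csv(report$subgroups,
      file.path(out_dir, "subgroups.csv"), progress = FALSE)
  }
  jsonlite::write_json(report$dfd, file.path(out_dir, "dfd.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Activity-sleep study report\n")
  cat(sprintf("  participants: %d total, %d included, %d with significant findings\n",
    x$counts$participants_total, x$counts$participants_included,
    x$counts$participants_with_significant_finding))
  cat(sprintf("  cases: %d complete, %d in included participants\n",
    x$counts$cases_total, x$counts$cases_included))
  if (!is.null(x$significant_subgroups) && nrow(x$significant_subgroups) > 0) {
    cat("  significant subgroups:\n")
    s <- x$significant_subgroups
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %s [%s]: %s (size %.0f%%, quality %.3f, p = %.4g)\n",
        s$scope[i], s$target[i], s$condition_text[i],
        100 * s$size_frac[i], s$quality[i], s$p_value[i]))
    }
  } else {
    cat("  no significant subgroups\n")
  }
  invisible(x)
}
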