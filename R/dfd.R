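#' Swap-randomize the target column of a case table
#'
#' Replaces the target with a uniform random permutation of its own values,
#' leaving every feature untouched, so the features' joint distribution is
#' preserved while any feature-target association is destroyed. With
#' `permute = "within"` values are permuted within participant, preserving
#' per-participant target distributions and case counts under the null.
#'
#' @param case_table Case table with at least 2 cases.
#' @param target Target column name.
#' @param seed Optional seed; omit to continue the current RNG stream.
#' @param permute `"global"` or `"within"` (within participant).
#' @return The case table with the target permuted.
#' @export
swap_randomize <- function(case_table, target = "light_sleep_s",
                           seed = NULL, permute = c("global", "within")) {
  permute <- match.arg(permute)
  stopifnot(nrow(case_table) >= 2, target %in% names(case_table))
  if (!is.null(seed)) set.seed(seed)
  y <- case_table[[target]]
  if (permute == "global") {
    case_table[[target]] <- y[sample.int(length(y))]
  } else {
    for (ix in split(seq_along(y), case_table$participant_id)) {
      case_table[[target]][ix] <- y[ix][sample.int(length(ix))]
    }
  }
  case_table
}

# Precompute the per-feature sort orders and distinct-value boundaries the
# C++ best-split kernel needs; the permutation loop reuses them.
split_geometry <- function(case_table, features) {
  n <- nrow(case_table)
  ord <- matrix(0L, n, length(features))
  bnd <- matrix(FALSE, n, length(features))
  for (j in seq_along(features)) {
    v <- as.numeric(case_table[[features[j]]])
    o <- order(v)
    ord[, j] <- o - 1L
    sv <- v[o]
    bnd[cum_distinct_counts(sv), j] <- TRUE
  }
  list(ord = ord, bnd = bnd)
}

#' Null distribution of best subgroup qualities
#'
#' The distribution of false discoveries: repeatedly swap-randomize the
#' target, re-run the full subgroup search under identical constraints, and
#' record the best explained variance of each permuted dataset. Locating
#' the observed best quality in this distribution accounts for the search
#' over all features and thresholds (the multiple-comparison problem of
#' subgroup discovery). The permutation stream is seeded once, so extending
#' `n_permutations` with the same seed leaves the initial null values
#' unchanged.
#'
#' @param case_table Case table for one scope.
#' @param target Target column name.
#' @param n_permutations Number of permutations, minimum 100; default 1000.
#' @param seed Seed for the permutation stream.
#' @param features,min_frac,max_frac Search constraints, as in
#'   [discover_best()].
#' @param permute `"global"` or `"within"` participant (see
#'   [swap_randomize()]).
#' @return Numeric vector of best qualities, one per permutation. A
#'   permutation with no admissible subgroup contributes quality 0 (with a
#'   warning).
#' @export
dfd_null <- function(case_table, target = "light_sleep_s",
                     n_permutations = 1000, seed = 1L, features = NULL,
                     min_frac = 0.10, max_frac = 0.90,
                     permute = c("global", "within")) {
  permute <- match.arg(permute)
  stopifnot(n_permutations >= 100)
  features <- features %||% intersect(feature_ids()$name, names(case_table))
  stopifnot(length(features) > 0, target %in% names(case_table))
  geom <- split_geometry(case_table, features)
  y <- as.numeric(case_table[[target]])
  groups <- if (permute == "within") {
    split(seq_along(y), case_table$participant_id)
  } else {
    list(seq_along(y))
  }
  set.seed(seed)
  qualities <- numeric(n_permutations)
  none <- 0L
  for (k in seq_len(n_permutations)) {
    yp <- y
    for (ix in groups) yp[ix] <- y[ix][sample.int(length(ix))]
    q <- cpp_best_split_ev(geom$ord, geom$bnd, yp, min_frac, max_frac)
    if (is.na(q)) {
      none <- none + 1L
      q <- 0
    }
    qualities[k] <- q
  }
  if (none > 0) {
    warning(none, " permutation(s) admitted no subgroup; quality recorded as 0")
  }
  qualities
}

#' Permutation p-value from a null distribution of best qualities
#'
#' Add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n)`: a valid
#' permutation p-value that is never exactly 0, with ties between null and
#' observed counted toward the numerator (conservative).
#'
#' @param observed Observed best quality.
#' @param null_qualities Non-empty numeric vector from [dfd_null()].
#' @return p-value in (0, 1].
#' @export
dfd_pvalue <- function(observed, null_qualities) {
  stopifnot(length(null_qualities) >= 1, !is.na(observed))
  (1 + sum(null_qualities >= observed)) / (1 + length(null_qualities))
}

#' Subgroup discovery with swap-randomization significance
#'
#' Runs [discover_best()] on the observed data, builds the null
#' distribution of best qualities with [dfd_null()], and reports the
#' permutation p-value. A finding is significant when the probability of
#' an equal-or-better quality arising from a target-randomized dataset is
#' strictly below `alpha`.
#'
#' @inheritParams dfd_null
#' @param alpha Significance level, default 0.05.
#' @return A list of class `dfd_result`: `target`, `best` (the
#'   [discover_best()] row), `observed_quality`, `null_qualities`,
#'   `n_permutations`, `p_value`, `significant`, `seed`, `permute`.
#'   `NULL` elements and `significant = FALSE` when no admissible subgroup
#'   exists in the observed data.
#' @export
dfd_test <- function(case_table, target = "light_sleep_s",
                     n_permutations = 1000, seed = 1L, alpha = 0.05,
                     features = NULL, min_frac = 0.10, max_frac = 0.90,
                     permute = c("global", "within")) {
  permute <- match.arg(permute)
  best <- discover_best(case_table, target, features = features,
    min_frac = min_frac, max_frac = max_frac)
  if (nrow(best) == 0) {
    return(structure(list(
      target = target, best = best, observed_quality = NA_real_,
      null_qualities = numeric(), n_permutations = 0L, p_value = NA_real_,
      significant = FALSE, seed = seed, permute = permute
    ), class = "dfd_result"))
  }
  nulls <- dfd_null(case_table, target, n_permutations = n_permutations,
    seed = seed, features = features, min_frac = min_frac,
    max_frac = max_frac, permute = permute)
  p <- dfd_pvalue(best$quality[1], nulls)
  structure(list(
    target = target, best = best, observed_quality = best$quality[1],
    null_qualities = nulls, n_permutations = length(nulls),
    p_value = p, significant = p < alpha, seed = seed, permute = permute
  ), class = "dfd_result")
}

#' Empirical type-I error of the subgroup significance test
#'
#' Generates independent null cohorts (no planted effect, so the target is
#' independent of every feature), runs discovery plus the
#' swap-randomization test on each, and reports the fraction declared
#' significant — an operational check that the nominal level holds.
#'
#' @param n_datasets Number of independent null datasets.
#' @param n_cases Cases per dataset (one synthetic participant with
#'   `n_cases + 3` fully observed days).
#' @param n_permutations Permutations per dataset.
#' @param alpha Significance level.
#' @param seed Master seed; per-dataset generation and permutation seeds
#'   are drawn from it.
#' @param target Target column tested.
#' @return A list: `rate` (empirical type-I error), `p_values`, `alpha`,
#'   `n_datasets`.
#' @export
calibrate_dfd <- function(n_datasets = 500, n_cases = 60,
                          n_permutations = 500, alpha = 0.05, seed = 1L,
                          target = "light_sleep_s") {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n_datasets),
    ncol = 2)
  cfg <- cohort_config(n_participants = 1,
    days_per_participant = n_cases + 3, missingness = 0)
  p_values <- vapply(seq_len(n_datasets), function(i) {
    cases <- build_cases(generate_cohort(cfg, seed = seeds[i, 1]))
    res <- dfd_test(cases, target = target,
      n_permutations = n_permutations, seed = seeds[i, 2], alpha = alpha)
    res$p_value
  }, numeric(1))
  list(rate = mean(p_values < alpha), p_values = p_values,
    alpha = alpha, n_datasets = n_datasets)
}
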