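#' Explained variance of a subgroup split
#'
#' Quality of a two-way split of cases into subgroup and complement:
#' `EV = 1 - SS_within / SS_total`, the fraction of target variance
#' explained by the split (between-group sum of squares over total sum of
#' squares). Algebraically identical to the squared point-biserial
#' correlation between membership and target, and invariant under
#' complementing the membership or affine-transforming the target.
#'
#' @param target Numeric target values for all cases.
#' @param membership Logical vector: `TRUE` for subgroup members. Both
#'   subgroup and complement must be non-empty.
#' @return EV in `[0, 1]`, or `NA` with a warning when the target is
#'   constant (`SS_total = 0`, quality undefined).
#' @export
explained_variance <- function(target, membership) {
  stopifnot(length(target) == length(membership),
    is.logical(membership), !anyNA(membership), !anyNA(target))
  n1 <- sum(membership)
  if (n1 == 0 || n1 == length(target)) {
    stop("subgroup and complement must both be non-empty")
  }
  ss_total <- sum((target - mean(target))^2)
  if (ss_total == 0) {
    warning("undefined quality: constant target (SS_total = 0)")
    return(NA_real_)
  }
  a <- target[membership]
  b <- target[!membership]
  ss_within <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  min(max(1 - ss_within / ss_total, 0), 1)
}

#' Enumerate admissible single-feature threshold conditions
#'
#' For each distinct observed value t of the feature, the candidates
#' `feature <= t` and `feature >= t` are formed; candidates whose subgroup
#' fraction falls outside `[min_frac, max_frac]` are discarded. Candidates
#' are already unique by induced membership: distinct prefixes (suffixes) of
#' the sorted order differ, and a prefix can only equal a suffix as the full
#' set, which the size bounds exclude.
#'
#' @param values Numeric feature values, `length(values) >= 10`.
#' @param min_frac,max_frac Subgroup-size bounds as fractions; default
#'   `(0.10, 0.90)`, inclusive.
#' @param feature Optional feature name recorded in the output.
#' @return Tibble with `feature`, `operator`, `threshold`, `n_cases`,
#'   `size_frac`.
#' @export
enumerate_conditions <- function(values, min_frac = 0.10, max_frac = 0.90,
                                 feature = NA_character_) {
  stopifnot(length(values) >= 10, !anyNA(values),
    min_frac > 0, min_frac < max_frac, max_frac < 1)
  n <- length(values)
  sv <- sort(values)
  b <- cum_distinct_counts(sv) # cumulative count at each distinct value
  v <- sv[b]
  le <- tibble::tibble(feature = feature, operator = "<=",
    threshold = v, n_cases = b)
  ge <- tibble::tibble(feature = feature, operator = ">=",
    threshold = v, n_cases = n - c(0L, head(b, -1L)))
  out <- rbind(le, ge)
  out$size_frac <- out$n_cases / n
  out[out$size_frac >= min_frac & out$size_frac <= max_frac, , drop = FALSE]
}

# Positions (1-based) in a sorted vector that close a run of equal values,
# i.e. cumulative counts of the distinct values.
cum_distinct_counts <- function(sv) {
  n <- length(sv)
  which(c(sv[-1] != sv[-n], TRUE))
}

# All admissible split candidates for one feature with their EV, computed in
# O(n log n) by a prefix-sum scan of the target in feature-sorted order.
# A split after sorted position m yields the prefix condition
# "<= sv[m]" (size m) and the suffix condition ">= sv[m + 1]" (size n - m);
# both induce the same partition, hence the same EV.
split_candidates <- function(v, y, min_frac, max_frac, feature,
                             ss_total, grand_sum) {
  n <- length(v)
  o <- order(v)
  sv <- v[o]
  cs <- cumsum(y[o])
  b <- cum_distinct_counts(sv)
  m <- b[b < n] # full set is never an admissible split
  if (length(m) == 0) return(NULL)
  between <- cs[m]^2 / m + (grand_sum - cs[m])^2 / (n - m) - grand_sum^2 / n
  ev <- pmin(pmax(between / ss_total, 0), 1)
  pre_ok <- m / n >= min_frac & m / n <= max_frac
  suf_ok <- (n - m) / n >= min_frac & (n - m) / n <= max_frac
  out <- NULL
  if (any(pre_ok)) {
    out <- tibble::tibble(feature = feature, operator = "<=",
      threshold = sv[m[pre_ok]], n_cases = m[pre_ok], quality = ev[pre_ok])
  }
  if (any(suf_ok)) {
    out <- rbind(out, tibble::tibble(feature = feature, operator = ">=",
      threshold = sv[m[suf_ok] + 1L], n_cases = n - m[suf_ok],
      quality = ev[suf_ok]))
  }
  out
}

# Deterministic candidate ordering: best quality first, ties broken by
# smaller subgroup, then "<=" before ">=", then smaller |threshold|, then
# feature name. A split and its complement share the same EV; the smaller
# side is the one whose target mean deviates more from the overall mean, so
# this convention reports the deviating side the condition describes.
order_candidates <- function(cand) {
  cand[order(-cand$quality, cand$n_cases, cand$operator,
    abs(cand$threshold), cand$feature), , drop = FALSE]
}

#' Find the best single-condition subgroup for a numeric target
#'
#' Exhaustively evaluates every admissible condition `feature <= t` /
#' `feature >= t` (t ranging over observed values of each feature) against
#' the explained-variance quality and returns the maximum-quality subgroup,
#' plus a ranked list. Exhaustive search over observed thresholds is exact:
#' it finds whatever an unlimited-width beam would find for depth-1 rules.
#' Ties are broken deterministically (smaller subgroup — the side deviating
#' more from the overall mean, which is how subgroup descriptions are
#' conventionally reported — then `<=` before `>=`, then smaller
#' `|threshold|`, then feature name).
#'
#' @param case_table Case table for a single scope (one participant, or the
#'   pooled standardized table); at least 10 cases.
#' @param target `"light_sleep_s"` or `"deep_sleep_s"` (any numeric column).
#' @param features Feature columns to search; defaults to all feature
#'   columns present.
#' @param min_frac,max_frac Subgroup-size bounds, default `(0.10, 0.90)`.
#' @param top_k Number of ranked subgroups to return (default 1).
#' @return A tibble of up to `top_k` rows: `feature`, `operator`,
#'   `threshold`, `target`, `n_cases`, `size_frac`, `quality`,
#'   `subgroup_mean`, `overall_mean`, `normalized_target_mean` (subgroup
#'   mean over overall mean; `NA` when the overall mean is not positive,
#'   e.g. standardized data) and `mean_difference`. Empty tibble when no
#'   admissible condition exists or the target is constant.
#' @export
discover_best <- function(case_table, target = "light_sleep_s",
                          features = NULL, min_frac = 0.10, max_frac = 0.90,
                          top_k = 1) {
  features <- features %||% intersect(feature_ids()$name, names(case_table))
  stopifnot(length(features) > 0, target %in% names(case_table),
    nrow(case_table) >= 10,
    min_frac > 0, min_frac < max_frac, max_frac < 1)
  y <- as.numeric(case_table[[target]])
  n <- length(y)
  ss_total <- sum((y - mean(y))^2)
  empty <- tibble::tibble(
    feature = character(), operator = character(), threshold = numeric(),
    target = character(), n_cases = integer(), size_frac = numeric(),
    quality = numeric(), subgroup_mean = numeric(), overall_mean = numeric(),
    normalized_target_mean = numeric(), mean_difference = numeric()
  )
  if (ss_total == 0) {
    warning("constant target: no subgroup quality defined")
    return(empty)
  }
  gs <- sum(y)
  cand <- dplyr::bind_rows(lapply(features, function(f) {
    split_candidates(as.numeric(case_table[[f]]), y, min_frac, max_frac,
      f, ss_total, gs)
  }))
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  cand <- order_candidates(cand)
  cand <- head(cand, top_k)

  overall <- mean(y)
  cand$target <- target
  cand$size_frac <- cand$n_cases / n
  cand$subgroup_mean <- vapply(seq_len(nrow(cand)), function(i) {
    v <- as.numeric(case_table[[cand$feature[i]]])
    mem <- if (cand$operator[i] == "<=") v <= cand$threshold[i] else
      v >= cand$threshold[i]
    mean(y[mem])
  }, numeric(1))
  cand$overall_mean <- overall
  cand$normalized_target_mean <- if (overall > 0) {
    cand$subgroup_mean / overall
  } else {
    NA_real_
  }
  cand$mean_difference <- cand$subgroup_mean - overall
  cand[, names(empty)]
}

#' Subgroup target mean relative to the whole scope
#'
#' Ratio of the subgroup's mean target value to the overall mean; above 1
#' means the subgroup sleeps longer than usual. On data whose overall mean
#' is not positive (e.g. standardized), the ratio is meaningless and `NA`
#' is returned with a warning; use the absolute mean difference instead.
#'
#' @param target Numeric target values for all cases in the scope.
#' @param membership Logical subgroup membership.
#' @return The ratio, or `NA` when the overall mean is not positive.
#' @export
normalized_target_mean <- function(target, membership) {
  stopifnot(length(target) == length(membership), sum(membership) > 0)
  overall <- mean(target)
  if (overall <= 0) {
    warning("overall mean not positive; ratio suppressed (use mean difference)")
    return(NA_real_)
  }
  mean(target[membership]) / overall
}
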