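#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). If either
#' vector has zero rank variance the correlation is undefined and `NA` is
#' returned with a warning (deliberately distinct from a zero correlation).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    warning("undefined Spearman correlation: zero rank variance")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' t-approximation p-value for a Spearman correlation
#'
#' Two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` referred to a
#' t distribution with `n - 2` degrees of freedom — the usual large-sample
#' test of zero correlation. For `|r| = 1` the statistic diverges and p is
#' reported as exactly 0.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param n Number of paired observations, `n >= 3`.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
spearman_p <- function(r, n) {
  if (any(n < 3)) stop("n must be at least 3")
  stopifnot(all(is.na(r) | abs(r) <= 1))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  p
}

#' Holm-Bonferroni step-down rejections
#'
#' Standard step-down procedure: order the p-values ascending and reject
#' while `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure;
#' decisions are mapped back to the input order. The family size `m` may
#' exceed the number of supplied p-values (tests not computed still count
#' toward the family).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`; `NA`s are never
#'   rejected and do not count toward the computed family size.
#' @param alpha Family-wise error rate, default 0.05.
#' @param m Family size; defaults to the number of non-missing p-values.
#' @return Logical vector of rejections, aligned with `pvalues`.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05, m = NULL) {
  stopifnot(length(pvalues) >= 1, alpha > 0, alpha < 1)
  ok <- !is.na(pvalues)
  stopifnot(all(pvalues[ok] >= 0 & pvalues[ok] <= 1))
  m <- m %||% sum(ok)
  adj <- rep(NA_real_, length(pvalues))
  adj[ok] <- stats::p.adjust(pvalues[ok], method = "holm", n = max(m, sum(ok)))
  !is.na(adj) & adj <= alpha
}

#' Qualitative strength of a correlation
#'
#' Conventional banding of `|r|`: below 0.10 negligible, 0.10 to below 0.40
#' weak, 0.40 to below 0.60 moderate, 0.60 and above strong.
#'
#' @param r Correlation(s), `|r| <= 1`.
#' @return Character vector of labels.
#' @export
strength_label <- function(r) {
  stopifnot(all(is.na(r) | abs(r) <= 1))
  labels <- c("negligible", "weak", "moderate", "strong")
  labels[findInterval(abs(r), c(0, 0.10, 0.40, 0.60))]
}

#' Spearman screening of all features against both sleep targets
#'
#' Correlates every lagged activity feature with light and deep sleep
#' duration, either per participant (`mode = "individual"`, on an
#' eligibility-filtered raw case table) or pooled (`mode = "group"`, on a
#' per-participant standardized table, scope `"GROUP"`). Within each scope
#' the Holm family spans all feature-target pairs (28 x 2 = 56 with the
#' default feature set). Per scope and target, the largest-`|r|` feature
#' among the Holm-significant ones is flagged as the headline result; when
#' nothing is significant the overall largest `|r|` is flagged instead (so
#' a null screen still reports its strongest, non-significant, finding).
#'
#' @param case_table A case table (standardized for group mode).
#' @param mode `"individual"` or `"group"`.
#' @param alpha Family-wise error rate, default 0.05.
#' @param family_size Holm family size per scope; defaults to the number of
#'   feature-target tests performed in that scope.
#' @return A tibble with one row per (scope, target, feature): `n`, `r`,
#'   `p`, `holm_reject`, `strength`, `headline`.
#' @export
run_correlation_screen <- function(case_table,
                                   mode = c("individual", "group"),
                                   alpha = 0.05, family_size = NULL) {
  mode <- match.arg(mode)
  feats <- intersect(feature_ids()$name, names(case_table))
  targets <- intersect(unname(sleep_targets), names(case_table))
  stopifnot(length(feats) > 0, length(targets) > 0)

  scopes <- if (mode == "group") {
    list(GROUP = case_table)
  } else {
    split(case_table, case_table$participant_id)
  }

  res <- lapply(names(scopes), function(sc) {
    tab <- scopes[[sc]]
    n <- nrow(tab)
    if (n < 3) {
      warning("scope ", sc, " has fewer than 3 cases; skipped")
      return(NULL)
    }
    grid <- expand.grid(feature = feats, target = targets,
      stringsAsFactors = FALSE)
    r <- suppressWarnings(vapply(seq_len(nrow(grid)), function(i) {
      xs <- tab[[grid$feature[i]]]
      ys <- tab[[grid$target[i]]]
      if (stats::sd(rank(xs)) == 0 || stats::sd(rank(ys)) == 0) {
        return(NA_real_)
      }
      stats::cor(xs, ys, method = "spearman")
    }, numeric(1)))
    p <- ifelse(is.na(r), NA_real_, spearman_p(r, n))
    rej <- holm_bonferroni(p, alpha = alpha, m = family_size)
    out <- tibble::tibble(
      scope = sc, target = grid$target, feature = grid$feature,
      n = n, r = r, p = p, holm_reject = rej,
      strength = ifelse(is.na(r), NA_character_, strength_label(r)),
      headline = FALSE
    )
    for (tg in targets) {
      ix <- which(out$target == tg & !is.na(out$r))
      if (length(ix) == 0) next
      sig <- ix[out$holm_reject[ix]]
      pool <- if (length(sig) > 0) sig else ix
      out$headline[pool[which.max(abs(out$r[pool]))]] <- TRUE
    }
    out
  })
  dplyr::bind_rows(res)
}
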