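# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (explicit loops, direct definitions) and
# never share code with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fixtures -------------------------------------------------------------

# A fully-observed daily-record tibble for one participant.
make_records <- function(pid, n_days, start = as.Date("2021-03-01"),
                         steps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    participant_id = pid,
    date = start + 0:(n_days - 1),
    steps = steps %||% round(runif(n_days, 1000, 9000)),
    light_activity_s = round(runif(n_days, 5000, 16000)),
    moderate_activity_s = round(runif(n_days, 300, 3000)),
    intense_activity_s = round(runif(n_days, 100, 2500)),
    light_sleep_s = round(runif(n_days, 9000, 18000)),
    deep_sleep_s = round(runif(n_days, 9000, 18000))
  )
}

# A random case table with arbitrary feature columns and both targets.
make_case_table <- function(n, n_features = 28, seed = 1,
                            pid = "P01") {
  set.seed(seed)
  fnames <- feature_ids()$name[seq_len(n_features)]
  tab <- tibble::tibble(
    participant_id = pid,
    date = as.Date("2021-03-01") + seq_len(n) - 1
  )
  for (f in fnames) tab[[f]] <- round(rnorm(n, 5000, 2000))
  tab$light_sleep_s <- rnorm(n, 13000, 2500)
  tab$deep_sleep_s <- rnorm(n, 13000, 2500)
  tab
}

# --- oracles --------------------------------------------------------------

# Spearman: explicit mid-rank then textbook Pearson formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Two-sided p-value by numerical integration of the t density.
oracle_t_pvalue <- function(r, n) {
  t_stat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  df <- n - 2
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * integrate(dens, t_stat, Inf, rel.tol = 1e-12)$value
}

# Holm: literal step-down loop over sorted p-values.
oracle_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) {
      reject[o[i]] <- TRUE
    } else {
      break
    }
  }
  reject
}

# Explained variance straight from the definition.
oracle_ev <- function(y, member) {
  ss <- function(v) sum((v - mean(v))^2)
  1 - (ss(y[member]) + ss(y[!member])) / ss(y)
}

# Brute-force best subgroup: loop over every feature, operator and observed
# threshold, score with oracle_ev, apply the size bounds and the tie-break
# (quality desc, smaller subgroup, "<=" first, smaller |threshold|, feature
# name) by explicit ordering.
oracle_discover <- function(tab, target, features, min_frac = 0.10,
                            max_frac = 0.90) {
  y <- as.numeric(tab[[target]])
  n <- length(y)
  rows <- list()
  for (f in features) {
    v <- as.numeric(tab[[f]])
    for (thr in sort(unique(v))) {
      for (op in c("<=", ">=")) {
        member <- if (op == "<=") v <= thr else v >= thr
        k <- sum(member)
        if (k / n < min_frac || k / n > max_frac) next
        rows[[length(rows) + 1]] <- data.frame(
          feature = f, operator = op, threshold = thr, n_cases = k,
          quality = oracle_ev(y, member), stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  cand <- do.call(rbind, rows)
  cand[order(-cand$quality, cand$n_cases, cand$operator,
    abs(cand$threshold), cand$feature), ][1, ]
}
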