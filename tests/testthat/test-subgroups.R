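test_that("explained variance follows its definition on hand-checked cases", {
  # equal subgroup and complement means -> nothing explained
  expect_equal(explained_variance(c(1, 3, 1, 3), c(TRUE, TRUE, FALSE, FALSE)), 0)
  # perfect separation
  expect_equal(explained_variance(c(5, 5, 9, 9), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # worked example: SS_total = 5, SS_within = 1 -> EV = 0.8
  expect_equal(explained_variance(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)),
    0.8)
  expect_error(explained_variance(1:4, rep(TRUE, 4)), "non-empty")
  expect_warning(ev <- explained_variance(rep(2, 4), c(TRUE, FALSE, TRUE, FALSE)),
    "undefined")
  expect_true(is.na(ev))
})

test_that("EV equals the squared point-biserial correlation and is invariant", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(10:80, 1)
    y <- rnorm(n)
    member <- sample(c(TRUE, FALSE), n, replace = TRUE,
      prob = c(0.4, 0.6))
    if (sum(member) == 0 || sum(member) == n) next
    ev <- explained_variance(y, member)
    expect_lt(abs(ev - cor(as.numeric(member), y)^2), 1e-10)
    # complement and positive-affine invariance
    expect_lt(abs(explained_variance(y, !member) - ev), 1e-12)
    expect_lt(abs(explained_variance(3.2 * y + 7, member) - ev), 1e-10)
  }
})

test_that("condition enumeration respects the size bounds", {
  # 10 distinct values: subgroup sizes 1..9 survive in each direction
  cond <- enumerate_conditions(1:10)
  expect_equal(nrow(cond), 18)
  expect_true(all(cond$size_frac >= 0.10 & cond$size_frac <= 0.90))
  # constant feature: only the full set is expressible -> nothing admissible
  expect_equal(nrow(enumerate_conditions(rep(3, 20))), 0)
  # random vector with ties: every retained fraction is in bounds and
  # matches a direct membership count
  set.seed(6)
  v <- sample(1:12, 50, replace = TRUE)
  cond <- enumerate_conditions(v)
  for (i in seq_len(nrow(cond))) {
    mem <- if (cond$operator[i] == "<=") v <= cond$threshold[i] else
      v >= cond$threshold[i]
    expect_equal(sum(mem), cond$n_cases[i])
    expect_gte(mean(mem), 0.10)
    expect_lte(mean(mem), 0.90)
  }
  # memberships are unique
  key <- paste(cond$operator, cond$n_cases)
  expect_equal(anyDuplicated(key), 0)
})

test_that("discover_best equals brute-force enumeration with the tie-break", {
  set.seed(7)
  for (i in 1:12) {
    n <- sample(c(15, 30, 60), 1)
    k <- sample(c(3, 6), 1)
    tab <- make_case_table(n, n_features = k, seed = 1000 + i)
    # coarse grid to force ties
    for (f in feature_ids()$name[seq_len(k)]) {
      tab[[f]] <- round(tab[[f]], -3)
    }
    feats <- feature_ids()$name[seq_len(k)]
    got <- discover_best(tab, "light_sleep_s", features = feats)
    want <- oracle_discover(tab, "light_sleep_s", feats)
    expect_equal(got$feature, want$feature)
    expect_equal(got$operator, want$operator)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$n_cases, want$n_cases)
    expect_equal(got$quality, want$quality, tolerance = 1e-10)
  }
})

test_that("discovery is deterministic and case-order invariant", {
  tab <- make_case_table(50, n_features = 10, seed = 88)
  a <- discover_best(tab, "deep_sleep_s")
  b <- discover_best(tab[sample(nrow(tab)), ], "deep_sleep_s")
  expect_equal(a, b)
})

test_that("relaxing the size bounds never decreases the best quality", {
  set.seed(14)
  for (i in 1:10) {
    tab <- make_case_table(40, n_features = 8, seed = 2000 + i)
    tight <- discover_best(tab, "light_sleep_s",
      min_frac = 0.10, max_frac = 0.90)
    loose <- discover_best(tab, "light_sleep_s",
      min_frac = 0.05, max_frac = 0.95)
    expect_gte(loose$quality, tight$quality)
  }
})

test_that("under independence the best quality vanishes with sample size", {
  tab <- make_case_table(10000, n_features = 28, seed = 90)
  best <- discover_best(tab, "light_sleep_s")
  expect_lt(best$quality, 0.01)
})

test_that("normalized target mean is the plain ratio of means", {
  y <- c(8, 8, 6, 6, 6, 6) * 3600
  mem <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(normalized_target_mean(y, mem), 8 / (40 / 6), tolerance = 1e-12)
  expect_equal(normalized_target_mean(y, rep(TRUE, 6)), 1)
  expect_warning(r <- normalized_target_mean(scale(y)[, 1], mem),
    "not positive")
  expect_true(is.na(r))
  # discover_best reports the same ratio it would get by recomputation
  tab <- make_case_table(60, n_features = 5, seed = 91)
  tab$light_sleep_s <- abs(tab$light_sleep_s)
  best <- discover_best(tab, "light_sleep_s",
    features = feature_ids()$name[1:5])
  v <- tab[[best$feature]]
  mem <- if (best$operator == "<=") v <= best$threshold else
    v >= best$threshold
  expect_equal(best$normalized_target_mean,
    mean(tab$light_sleep_s[mem]) / mean(tab$light_sleep_s),
    tolerance = 1e-12)
})

test_that("the R search and the compiled permutation kernel agree", {
  set.seed(17)
  for (i in 1:10) {
    tab <- make_case_table(45, n_features = 12, seed = 3000 + i)
    feats <- feature_ids()$name[1:12]
    best <- discover_best(tab, "deep_sleep_s", features = feats)
    geom <- actisleep:::split_geometry(tab, feats)
    fast <- actisleep:::cpp_best_split_ev(geom$ord, geom$bnd,
      as.numeric(tab$deep_sleep_s), 0.10, 0.90)
    expect_equal(fast, best$quality, tolerance = 1e-12)
  }
})
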