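# Statistical battery: t tests, ROC, logistic combinations, ICC, summaries.

test_that("compare_groups: identity, scale invariance, degenerate input", {
  x <- c(1.2, 1.5, 1.1, 1.9, 1.4)
  same <- compare_groups(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  a <- rnorm(30); b <- rnorm(30, 0.5)
  g1 <- compare_groups(a, b)
  g2 <- compare_groups(10 * a, 10 * b)
  expect_equal(g1$t_stat, g2$t_stat, tolerance = 1e-12)
  expect_equal(g1$p_value, g2$p_value, tolerance = 1e-12)
  deg <- compare_groups(rep(1, 5), rep(1, 7))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("t-test rejection rate matches closed-form power", {
  set.seed(31)
  n_rep <- 1000
  rej <- mean(replicate(n_rep, {
    compare_groups(rnorm(50, 0), rnorm(50, 1))$p_value < 0.05
  }))
  pow <- stats::power.t.test(n = 50, delta = 1, sd = 1,
                             sig.level = 0.05)$power
  expect_lt(abs(rej - pow), 3 * sqrt(pow * (1 - pow) / n_rep) + 1e-3)
})

test_that("empirical AUC equals the Mann-Whitney concordance exactly", {
  concordance <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    s <- sample(round(rnorm(n), sample(0:2, 1)))  # ties included
    r <- roc_analysis(s, y, positive = TRUE)
    cc <- concordance(s, y)
    expect_equal(r$auc, max(cc, 1 - cc), tolerance = 1e-12)
  }
})

test_that("ROC: perfect separation, orientation, cutoff semantics", {
  s <- c(1, 2, 3, 10, 11, 12)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(s, y, positive = TRUE)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_true(r$cutoff > 3 && r$cutoff < 10)
  # label inversion maps auc -> 1 - auc before orientation correction
  rin <- roc_analysis(s, !y, positive = TRUE)
  expect_equal(rin$auc, 1)
  expect_equal(rin$orientation, "lower_positive")
  expect_error(roc_analysis(s, rep(TRUE, 6)), "both classes")
})

test_that("logistic combinations: single feature, noise feature, separation", {
  set.seed(23)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x1 <- rnorm(n, ifelse(y, 0.8, 0))
  single <- logistic_combination(cbind(x1), y, positive = TRUE)
  expect_equal(single$roc$auc, roc_analysis(x1, y, positive = TRUE)$auc,
               tolerance = 1e-12)  # monotone transform invariance
  for (s in 1:3) {
    set.seed(100 + s)
    noise <- rnorm(n)
    both <- logistic_combination(cbind(x1, noise), y, positive = TRUE)
    expect_gte(both$roc$auc, single$roc$auc - 1e-9)
  }
  # perfect separation falls back to a penalized fit, flagged
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(FALSE, TRUE), each = 20)
  sep <- logistic_combination(cbind(xs), ys, positive = TRUE)
  expect_true(sep$separation)
  expect_equal(sep$roc$auc, 1)
})

test_that("ICC(2,1): identity, null, calibrated observer noise", {
  x <- rnorm(50)
  expect_equal(icc_reliability(x, x)$icc, 1, tolerance = 1e-9)
  set.seed(41)
  null <- icc_reliability(rnorm(100), rnorm(100))
  expect_true(null$icc > -0.2 && null$icc < 0.2)
  # truth + observer noise at variance ratio 1:0.2 -> ICC ~ 1/1.2
  truth <- rnorm(200)
  tau <- sqrt(0.2)
  cal <- icc_reliability(truth + rnorm(200, 0, tau),
                         truth + rnorm(200, 0, tau))
  expect_true(cal$icc > 0.75 && cal$icc < 0.95)
  expect_true(cal$ci_low <= cal$icc && cal$icc <= cal$ci_high)
  const <- icc_reliability(rep(1, 10), rep(1, 10))
  expect_true(const$flagged)
})

test_that("summarize_cohort computes printed-style percentages", {
  exc <- apply_exclusions(generate_roster(cohort_spec(), seed = 1))
  comp <- summarize_cohort(exc$cohort)
  pick <- function(f, l) comp$pct[comp$field == f & comp$level == l]
  expect_equal(pick("er", "pos"), 74.36)
  expect_equal(pick("ki67", "high"), 88.89)
  # exhaustive categories sum to 100 up to rounding
  for (f in unique(comp$field))
    expect_equal(sum(comp$pct[comp$field == f]), 100, tolerance = 0.02)
  expect_error(summarize_cohort(exc$cohort[0, ]), "empty")
})

test_that("permuting labels destroys group differences", {
  set.seed(53)
  a <- rnorm(60, 1); b <- rnorm(60, 0)
  expect_lt(compare_groups(a, b)$p_value, 0.01)
  pooled <- c(a, b)
  p_perm <- replicate(51, {
    idx <- sample(120, 60)
    compare_groups(pooled[idx], pooled[-idx])$p_value
  })
  expect_gt(median(p_perm), 0.3)
})

test_that("reports have the contracted shape and a null grade contrast", {
  res <- run_cohort_analysis(small_spec(), test_prot(), seed = 19, snr = Inf,
                             n_vox = 2, kernel = test_kernel())
  rep <- build_reports(res$cohort)
  # one comparison row per contrast x parameter
  n_contrast <- length(unique(rep$table4$contrast))
  expect_equal(nrow(rep$table4), n_contrast * 8)
  expect_true(all(rep$table4$p_value >= 0 & rep$table4$p_value <= 1,
                  na.rm = TRUE))
  expect_true(all(c("p_bh", "stars") %in% names(rep$table4)))
  # grade does not enter the generator: its contrast behaves like a null
  # (at most chance-level significance across the eight parameters)
  grade <- rep$table4[rep$table4$contrast == "grade", ]
  if (nrow(grade)) expect_lte(sum(grade$p_value < 0.05), 2)
  # combinations present for their contrasts
  expect_true("Comb1" %in% rep$table5$marker)
})
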