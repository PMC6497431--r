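test_that("roc_auc equals the all-pairs concordance probability", {
  expect_equal(roc_auc(c(10, 11), c(1, 2)), 1)
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  x <- c(1, 2, 2, 7)
  expect_equal(roc_auc(x, x), 0.5)
  expect_error(roc_auc(numeric(0), 1), class = "methrisk_domain_error")

  set.seed(101)
  for (i in 1:300) {
    pos <- sample(0:8, sample(2:9, 1), replace = TRUE)
    neg <- sample(0:8, sample(2:9, 1), replace = TRUE)
    expect_equal(roc_auc(pos, neg), oracle_auc(pos, neg), tolerance = 1e-12)
    # complement symmetry with the half-tie convention
    expect_equal(roc_auc(pos, neg) + roc_auc(neg, pos), 1, tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    pos <- round(runif(15, 0, 5), 1); neg <- round(runif(20, 0, 5), 1)
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(c(rep(1, 15), rep(0, 20)), c(pos, neg),
                          quiet = TRUE, direction = "<"))))
    expect_equal(roc_auc(pos, neg), ref, tolerance = 1e-10)
  }
})

test_that("youden_cutoff maximises J over observed values, ties to larger theta", {
  r <- youden_cutoff(c(10, 12, 14), c(1, 2, 3))
  expect_equal(r$threshold, 10)
  expect_equal(r$sensitivity + r$specificity - 1, 1)

  r2 <- youden_cutoff(c(2, 5, 6), c(1, 2, 3))
  expect_equal(r2$threshold, 5)
  expect_equal(r2$sensitivity, 2 / 3)
  expect_equal(r2$specificity, 1)

  x <- c(1, 3, 3, 8)
  r3 <- youden_cutoff(x, x)
  expect_equal(r3$threshold, 8)   # J = 0 everywhere; tie-break to max
  expect_equal(r3$sensitivity + r3$specificity - 1, 0)
})

test_that("youden scan equals the exhaustive oracle and is rank-invariant", {
  set.seed(33)
  for (i in 1:100) {
    pos <- round(runif(sample(3:15, 1), 0, 10), 1)
    neg <- round(runif(sample(3:15, 1), 0, 10), 1)
    r <- youden_cutoff(pos, neg)
    o <- oracle_youden(pos, neg)
    expect_equal(r$threshold, o$theta)
    expect_equal(r$sensitivity + r$specificity - 1, o$j, tolerance = 1e-12)
    # invariance under a strictly increasing transform
    f <- function(x) exp(x / 4) + x
    rt <- youden_cutoff(f(pos), f(neg))
    expect_equal(rt$threshold, f(o$theta))
    expect_equal(rt$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("proportion_above uses >= and one-decimal reporting", {
  vals <- c(rep(10, 48), rep(1, 10))  # 48 of 58 at or above 5
  expect_equal(proportion_above(vals, 5), 82.8)
  expect_equal(proportion_above(c(1, 2), 5), 0)
  expect_equal(proportion_above(c(5, 5, 5), 5), 100)
})

test_that("minimum-p log-rank scan matches brute force and honours eligibility", {
  # no survival information: single shared event time
  r <- minp_logrank_cutoff(c(1, 2, 3, 4), rep(5, 4), rep(TRUE, 4),
                           min_group_frac = 0.2)
  expect_false(r$found)

  # perfectly informative split at 10
  vals <- c(10, 10, 10, 1, 1, 1)
  times <- c(1, 2, 3, 60, 60, 60)
  ev <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r2 <- minp_logrank_cutoff(vals, times, ev, min_group_frac = 0.2)
  o <- oracle_minp_logrank(vals, times, ev, 0.2)
  expect_true(r2$found)
  expect_equal(r2$threshold, 10)
  expect_equal(r2$scan_p, o$p, tolerance = 1e-12)
  expect_gt(r2$relative_risk, 1)

  # candidates leaving a group below ceil(frac*n) are skipped
  vals3 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  set.seed(5)
  times3 <- rexp(10, 0.05); ev3 <- rep(TRUE, 10)
  r3 <- minp_logrank_cutoff(vals3, times3, ev3, min_group_frac = 0.2,
                            alpha = 1)
  scan <- r3$scan[[1]]
  expect_false(any(scan$threshold %in% c(1, 2, 10)))  # would leave < 2 members

  set.seed(19)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    v <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
    tm <- round(rexp(n, 0.03), 2)
    e <- runif(n) < 0.8
    if (length(unique(v)) < 3 || !any(e)) next
    o <- oracle_minp_logrank(v, tm, e, 0.15)
    r <- minp_logrank_cutoff(v, tm, e, min_group_frac = 0.15, alpha = 1)
    if (is.null(o)) { expect_false(r$found); next }
    expect_equal(r$threshold, o$theta)
    expect_equal(r$scan_p, o$p, tolerance = 1e-10)
  }
})

test_that("an induced hazard switch is recovered by the log-rank scan", {
  set.seed(77)
  hits <- replicate(200, {
    n <- 200
    v <- sample(seq(1, 40, by = 1), n, replace = TRUE)
    rate <- ifelse(v >= 20, 0.08, 0.01)
    t_lat <- rexp(n, rate)
    tm <- pmin(t_lat, 60); e <- t_lat <= 60
    r <- minp_logrank_cutoff(v, tm, e, min_group_frac = 0.1)
    isTRUE(r$found) && r$threshold >= 15 && r$threshold <= 25
  })
  expect_gte(mean(hits), 0.9)
})

test_that("minimum-p t-test scan matches brute force", {
  vals <- c(0.1, 0.1, 0.2, 1.0, 1.1, 1.2)
  terms <- c(120, 130, 110, 40, 50, 45)
  r <- minp_ttest_cutoff(vals, terms, min_group_frac = 0.15)
  o <- oracle_minp_ttest(vals, terms, 0.15)
  expect_true(r$found)
  expect_equal(r$threshold, 1.0)
  expect_equal(r$scan_p, o$p, tolerance = 1e-12)
  expect_equal(r$n_short, 3); expect_equal(r$n_long, 3)
  expect_equal(r$mean_short, 45); expect_equal(r$mean_long, 120)

  expect_false(minp_ttest_cutoff(rep(2, 6), terms)$found)

  set.seed(55)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    v <- sample(seq(0, 3, by = 0.25), n, replace = TRUE)
    trm <- round(runif(n, 10, 300), 1)
    if (length(unique(v)) < 3) next
    o <- oracle_minp_ttest(v, trm, 0.15)
    r <- minp_ttest_cutoff(v, trm, min_group_frac = 0.15)
    if (is.null(o)) { expect_false(r$found); next }
    expect_equal(r$threshold, o$theta)
    expect_equal(r$scan_p, o$p, tolerance = 1e-10)
  }
})

test_that("uncorrected minimum-p selection is anti-conservative under the null", {
  set.seed(99)
  pmins <- replicate(300, {
    v <- sample(seq(0, 3, by = 0.25), 24, replace = TRUE)
    trm <- rnorm(24, 100, 40)        # terms independent of values
    r <- minp_ttest_cutoff(v, trm, min_group_frac = 0.15)
    if (isTRUE(r$found)) r$scan_p else NA_real_
  })
  pmins <- pmins[!is.na(pmins)]
  # stochastically below uniform: far more than 5% land under 0.05
  expect_gt(mean(pmins < 0.05), 0.10)
  expect_lt(median(pmins), 0.35)
  # and the permutation adjustment pulls the selected p back up
  set.seed(100)
  v <- sample(seq(0, 3, by = 0.25), 24, replace = TRUE)
  trm <- rnorm(24, 100, 40)
  r <- minp_ttest_cutoff(v, trm, min_group_frac = 0.15, n_perm = 200)
  expect_gte(r$scan_p_adjusted, r$scan_p)
})

test_that("data-frame wrappers scan per gene over the right compartments", {
  cfg <- generator_config(seed = 12)
  co <- generate_cohort(cfg)
  bx <- generate_biopsy_series(co$patients, cfg)
  diag <- find_diagnostic_cutoffs(co$samples)
  expect_equal(diag$gene, c("CDO1", "HOPX", "Reprimo", "ECAD"))
  expect_true(all(diag$found))
  expect_true(all(diag$auc >= 0 & diag$auc <= 1))
  expect_true(all(diag$pct_tumor_above >= diag$pct_mucosa_above))

  trm <- find_term_cutoffs(bx)
  expect_equal(nrow(trm), 4)
  os <- find_survival_cutoffs(co$samples, co$patients, "os")
  expect_equal(nrow(os), 4)
  expect_true(all(is.na(os$threshold[!os$found])))
})
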