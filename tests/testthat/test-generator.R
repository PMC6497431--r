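test_that("log-normal moment matching recovers target moments by sampling", {
  # degenerate limit: zero SD collapses to a point mass at m
  par0 <- lognormal_from_moments(7, 0)
  expect_equal(unname(par0), c(log(7), 0))
  expect_error(lognormal_from_moments(-1, 1), class = "methrisk_domain_error")

  par <- lognormal_from_moments(16.90, 12.08)
  expect_equal(unname(par), c(2.6208, 0.6426), tolerance = 1e-3)
  set.seed(1)
  for (ms in list(c(16.90, 12.08), c(3.71, 4.74))) {
    p <- lognormal_from_moments(ms[1], ms[2])
    x <- stats::rlnorm(1e6, p["meanlog"], p["sdlog"])
    expect_lt(abs(mean(x) - ms[1]) / ms[1], 0.01)
    expect_lt(abs(sd(x) - ms[2]) / ms[2], 0.02)
  }
})

test_that("zero-inflation calibration matches printed exceedance fractions", {
  # RT CDO1: published 82.8% of tumors at or above 6.49
  pi0 <- calibrate_zero_inflation(16.90, 12.08, 6.49, 0.828)
  par <- methrisk:::zi_lognormal_params(16.90, 12.08, pi0)
  tail_p <- (1 - pi0) * plnorm(6.49, par["meanlog"], par["sdlog"],
                               lower.tail = FALSE)
  expect_lt(abs(tail_p - 0.828), 0.005)
  # infeasible target (0%) returns the closest feasible mass, not an error
  pi0_ecad <- calibrate_zero_inflation(0.081, 0.19, 1.09, 0)
  expect_gte(pi0_ecad, 0)
  expect_lt(pi0_ecad, 1)
})

test_that("cohorts are deterministic given the seed", {
  cfg <- generator_config(seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$samples, b$samples)
  set.seed(5); bx1 <- generate_biopsy_series(a$patients, cfg)
  set.seed(5); bx2 <- generate_biopsy_series(b$patients, cfg)
  expect_identical(bx1, bx2)
})

test_that("onset terms match the truncated-normal means at large n", {
  cfg <- generator_config(seed = 21, n_malignant = 10000, n_benign = 10000)
  co <- generate_cohort(cfg)
  tm <- co$patients$term_to_rgc[co$patients$initial_diagnosis == "MALIGNANT"]
  tb <- co$patients$term_to_rgc[co$patients$initial_diagnosis == "BENIGN"]
  expect_true(all(co$patients$term_to_rgc > 0))
  mu_m <- truncnorm_mean(191.5, 127.5, 1)
  mu_b <- truncnorm_mean(485.7, 86.7, 1)
  expect_lt(abs(mean(tm) - mu_m), 3 * sd(tm) / sqrt(length(tm)))
  expect_lt(abs(mean(tb) - mu_b), 3 * sd(tb) / sqrt(length(tb)))
})

test_that("copula induces trio correlation and leaves E-cadherin independent", {
  cfg <- generator_config(seed = 3)
  set.seed(3)
  x <- sample_methylation(1e4, "RT", cfg)
  rho_ch <- cor(x$CDO1, x$HOPX, method = "spearman")
  rho_ce <- cor(x$CDO1, x$ECAD, method = "spearman")
  expect_gt(rho_ch, 0.4); expect_lt(rho_ch, 0.7)
  expect_gt(rho_ce, -0.1); expect_lt(rho_ce, 0.1)
})

test_that("generator recovers configured moments within 2% at n = 1e5", {
  cfg <- generator_config(seed = 17)
  params <- default_methylation_params()
  set.seed(17)
  n <- 1e5
  for (cell in unique(params$cell)) {
    x <- sample_methylation(n, cell, cfg)
    for (g in c("CDO1", "HOPX", "Reprimo", "ECAD")) {
      row <- params[params$cell == cell & params$gene == g, ]
      expect_lt(abs(mean(x[[g]]) - row$m) / row$m, 0.02,
                label = sprintf("mean rel.err %s/%s", cell, g))
      # the SD estimator's own sampling error dominates 2% for the
      # heaviest-tailed cells; budget 4 analytic standard errors
      sd_tol <- max(0.02 * row$s, 4 * zi_ln_se_sd(row$m, row$s, row$pi0, n))
      expect_lt(abs(sd(x[[g]]) - row$s), sd_tol,
                label = sprintf("sd abs.err %s/%s", cell, g))
      expect_true(all(x[[g]] >= 0))
    }
  }
})

test_that("biopsy coupling drives a weak negative value-time association", {
  cfg0 <- generator_config(seed = 8, n_malignant = 1500, n_benign = 10,
                           n_biopsy_patients = 1000, n_biopsies = 2000,
                           biopsy_coupling = c(CDO1 = 0, HOPX = 0,
                                               Reprimo = 0, ECAD = 0))
  co <- generate_cohort(cfg0)
  bx0 <- generate_biopsy_series(co$patients, cfg0)
  r2_0 <- linear_r2(bx0$months_before_onset, bx0$HOPX)$r2
  expect_lt(r2_0, 0.01)   # no coupling, no signal

  cfg1 <- generator_config(seed = 8, n_malignant = 1500, n_benign = 10,
                           n_biopsy_patients = 1000, n_biopsies = 2000)
  co1 <- generate_cohort(cfg1)
  bx1 <- generate_biopsy_series(co1$patients, cfg1)
  fit <- linear_r2(bx1$months_before_onset, bx1$HOPX)
  expect_gt(fit$r2, 0.05); expect_lt(fit$r2, 0.20)
  expect_equal(fit$slope_sign, -1)
  expect_true(all(bx1$months_before_onset > 0))
  expect_true(all(bx1$months_before_onset <
                    co1$patients$term_to_rgc[match(bx1$patient_id,
                                                   co1$patients$patient_id)]))

  expect_error(generator_config(seed = 1, biopsy_coupling = c(
    CDO1 = 1.2, HOPX = 0, Reprimo = 0, ECAD = 0)),
    class = "methrisk_config_error")
})

test_that("zero hazard censors everyone at the follow-up horizon", {
  cfg <- generator_config(seed = 2, base_rate_os = 0)
  co <- generate_cohort(cfg)
  expect_true(all(co$patients$os_time == 60))
  expect_false(any(co$patients$os_event))
  expect_false(any(co$patients$rfs_event))
})

test_that("stage hazard ratio is recoverable by Cox at n = 200 per arm", {
  cfg <- generator_config(seed = 31, n_malignant = 200, n_benign = 200,
                          p_stage_ge_iii = 0.5, hr_stage = 3)
  co <- generate_cohort(cfg)
  hi <- as.integer(co$patients$stage %in% c("III", "IV"))
  fit <- cox_fit(co$patients$os_time, co$patients$os_event,
                 data.frame(stage_hi = hi))
  hr <- fit$coefficients$hr[1]
  expect_gt(hr, 2.2); expect_lt(hr, 4.0)
})

test_that("with equal hazards the log-rank p-value is uniform", {
  cfg <- generator_config(seed = 41, n_malignant = 30, n_benign = 30,
                          hr_stage = 1)
  base <- tibble::tibble(
    initial_diagnosis = rep(c("MALIGNANT", "BENIGN"), each = 30),
    stage = "II")
  set.seed(41)
  pvals <- replicate(500, {
    pat <- generate_survival(base, cfg)
    g <- pat$initial_diagnosis == "MALIGNANT"
    logrank_test(pat$os_time[g], pat$os_event[g],
                 pat$os_time[!g], pat$os_event[!g])$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
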