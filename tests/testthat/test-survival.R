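test_that("Kaplan-Meier matches the product-limit risk table", {
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  km2 <- kaplan_meier(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_true(all(km2$surv == 1))
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)),
               class = "methrisk_domain_error")

  # mixed events/censoring against a hand-computed table:
  # t=2: 5 at risk, 1 event -> 4/5; t=4 (censor) no step;
  # t=6: 3 at risk, 1 event -> 4/5 * 2/3; t=9: 1 at risk, 1 event -> 0
  km3 <- kaplan_meier(c(2, 4, 6, 7, 9), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  ev <- km3[km3$n_event > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(3)
  for (i in 1:20) {
    tm <- sample(1:40, sample(5:25, 1), replace = TRUE)
    km <- kaplan_meier(tm, rep(TRUE, length(tm)))
    emp <- vapply(km$time, function(t) mean(tm > t), numeric(1))
    expect_equal(km$surv, emp, tolerance = 1e-12)
  }
})

test_that("log-rank equals the hand risk-table statistic and is symmetric", {
  ident <- logrank_test(c(1, 2, 3), c(TRUE, TRUE, TRUE),
                        c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(ident$chi2, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1)

  r <- logrank_test(c(1, 2), c(TRUE, TRUE), c(3, 4), c(TRUE, TRUE))
  expect_equal(r$chi2, oracle_logrank_chi2(c(1, 2), c(TRUE, TRUE),
                                           c(3, 4), c(TRUE, TRUE)),
               tolerance = 1e-9)
  expect_equal(r$chi2, 2.882, tolerance = 1e-3)

  set.seed(9)
  for (i in 1:30) {
    nA <- sample(4:15, 1); nB <- sample(4:15, 1)
    tA <- round(rexp(nA, 0.05), 3); tB <- round(rexp(nB, 0.08), 3)
    eA <- runif(nA) < 0.8; eB <- runif(nB) < 0.8
    if (!any(c(eA, eB))) next
    r1 <- logrank_test(tA, eA, tB, eB)
    expect_equal(r1$chi2, oracle_logrank_chi2(tA, eA, tB, eB),
                 tolerance = 1e-8)
    r2 <- logrank_test(tB, eB, tA, eA)
    expect_equal(r1$chi2, r2$chi2, tolerance = 1e-12)
  }

  expect_warning(r0 <- logrank_test(c(1, 2), c(FALSE, FALSE),
                                    c(3, 4), c(FALSE, FALSE)))
  expect_equal(r0$p, 1)
})

test_that("log-rank equals the Cox score test on a binary covariate", {
  set.seed(13)
  for (i in 1:20) {
    n <- 40
    g <- rbinom(n, 1, 0.5)
    tm <- rexp(n, 0.02 * exp(0.7 * g)) + cumsum(rep(1e-4, n))  # untied
    e <- runif(n) < 0.85
    if (sum(g) < 2 || sum(!g) < 2 || !any(e)) next
    lr <- logrank_test(tm[g == 1], e[g == 1], tm[g == 0], e[g == 0])
    cox <- survival::coxph(survival::Surv(tm, e) ~ g)
    expect_equal(lr$chi2, unname(cox$score), tolerance = 1e-8)
  }
})

test_that("Cox recovers a simulated hazard ratio and rejects constants", {
  set.seed(17)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t_lat <- rexp(n, 0.02 * 3^x)
  tm <- pmin(t_lat, 60); e <- t_lat <= 60
  fit <- cox_fit(tm, e, data.frame(marker = x))
  expect_gt(fit$coefficients$hr[1], 2.2)
  expect_lt(fit$coefficients$hr[1], 4.0)
  expect_true(fit$coefficients$ci_low[1] <= fit$coefficients$hr[1])
  expect_true(fit$coefficients$ci_high[1] >= fit$coefficients$hr[1])
  expect_error(cox_fit(tm, e, data.frame(k = rep(1, n))),
               class = "methrisk_domain_error")
  td <- tidy(fit); gl <- glance(fit)
  expect_identical(td$term, "marker")
  expect_equal(gl$n, n)
})

test_that("null-covariate Cox confidence intervals cover 1 at nominal rate", {
  set.seed(19)
  cover <- replicate(200, {
    n <- 120
    x <- rnorm(n)
    t_lat <- rexp(n, 0.03)
    tm <- pmin(t_lat, 60); e <- t_lat <= 60
    f <- cox_fit(tm, e, data.frame(x = x))
    f$coefficients$ci_low[1] <= 1 && f$coefficients$ci_high[1] >= 1
  })
  expect_gt(mean(cover), 0.88)
  expect_lte(mean(cover), 1)
})

test_that("prognostic workflow screens univariately and excludes TNM under stage", {
  set.seed(23)
  n <- 300
  stage <- sample(c("I", "II", "III"), n, replace = TRUE)
  hi <- stage == "III"
  depth <- ifelse(hi | runif(n) < 0.3, "MP_OR_DEEPER", "SM_OR_LESS")
  t_lat <- rexp(n, 0.01 * ifelse(hi, 6, 1))
  df <- tibble::tibble(
    stage = stage, depth_T = depth,
    lauren = sample(c("INTESTINAL", "DIFFUSE"), n, replace = TRUE),
    os_time = pmin(t_lat, 60), os_event = t_lat <= 60)
  wf <- prognostic_workflow(df, "os_time", "os_event",
                            categorical = c("stage", "depth_T", "lauren"))
  sc <- wf$screen
  expect_true(sc$significant[sc$factor == "stage"])
  expect_true(sc$significant[sc$factor == "depth_T"])
  expect_true(sc$excluded_tnm[sc$factor == "depth_T"])    # constituent of stage
  expect_false(sc$enters_multivariate[sc$factor == "depth_T"])
  expect_true(sc$enters_multivariate[sc$factor == "stage"])
  expect_false(is.null(wf$multivariate))
  expect_false("depth_T" %in% sub("[A-Z]+$", "", tidy(wf$multivariate)$term))

  # nothing informative: report-only output
  df0 <- df |> dplyr::mutate(os_time = pmin(rexp(n, 0.02), 60),
                             os_event = os_time < 60)
  wf0 <- prognostic_workflow(df0, "os_time", "os_event",
                             categorical = "lauren")
  if (!wf0$screen$significant[1]) expect_null(wf0$multivariate)
})

test_that("a marker riding on a dominant stage effect is usually eliminated", {
  set.seed(29)
  elim <- replicate(200, {
    n <- 150
    hi <- rbinom(n, 1, 0.3)
    stage <- ifelse(hi == 1, "III", "II")
    marker_hi <- ifelse(runif(n) < ifelse(hi == 1, 0.8, 0.2), "HIGH", "LOW")
    t_lat <- rexp(n, 0.01 * ifelse(hi == 1, 5, 1))
    df <- tibble::tibble(stage = stage, marker = marker_hi,
                         os_time = pmin(t_lat, 60), os_event = t_lat <= 60)
    wf <- prognostic_workflow(df, "os_time", "os_event",
                              categorical = c("stage", "marker"))
    sc <- wf$screen
    if (!sc$significant[sc$factor == "marker"]) return(NA)
    mv <- tidy(wf$multivariate)
    mk <- mv[grepl("marker", mv$term), ]
    st <- mv[grepl("stage", mv$term), ]
    nrow(mk) == 1 && mk$p > 0.05 && st$p < 0.05
  })
  elim <- elim[!is.na(elim)]
  expect_gt(mean(elim), 0.5)
})
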