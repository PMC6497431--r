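test_that("gene points follow the at-or-above rule and propagate missingness", {
  expect_identical(gene_point(1.19, 1.2), 0L)
  expect_identical(gene_point(1.2, 1.2), 1L)
  expect_identical(gene_point(5.0, 0.60), 1L)
  expect_identical(gene_point(NA_real_, 1.2), NA_integer_)
  expect_error(gene_point(1, 0), class = "methrisk_domain_error")
  expect_error(gene_point(-1, 1), class = "methrisk_domain_error")
})

test_that("sample scoring sums subset points with complete-flag semantics", {
  th <- c(CDO1 = 1.2, HOPX = 0.60, Reprimo = 0.15, ECAD = 0.07)
  s <- tibble::tibble(patient_id = "P1", compartment = "RN",
                      months_before_onset = NA_real_,
                      CDO1 = 1.3, HOPX = 0.50, Reprimo = 0.20, ECAD = 0.00)
  sc <- score_samples(s, th)
  expect_identical(c(sc$pt_CDO1, sc$pt_HOPX, sc$pt_Reprimo, sc$pt_ECAD),
                   c(1L, 0L, 1L, 0L))
  expect_identical(sc$total, 2L)
  expect_true(sc$complete)

  s0 <- s |> dplyr::mutate(CDO1 = 0, HOPX = 0, Reprimo = 0, ECAD = 0)
  expect_identical(score_samples(s0, th)$total, 0L)

  s_na <- s |> dplyr::mutate(ECAD = NA_real_)
  sc3 <- score_samples(s_na, th, genes = c("CDO1", "HOPX", "Reprimo"))
  expect_true(sc3$complete)          # ECAD not in the scored subset
  expect_identical(sc3$total, 2L)
  sc4 <- score_samples(s_na, th)
  expect_false(sc4$complete)         # missing gene: lower-bound total

  expect_error(score_samples(s, th, genes = c("CDO1", "TP53")),
               class = "methrisk_config_error")
  expect_error(score_samples(s, th[1:3]), class = "methrisk_config_error")
})

test_that("totals equal a brute-force count on random panels; score is monotone", {
  th <- c(CDO1 = 1.2, HOPX = 0.60, Reprimo = 0.15, ECAD = 0.07)
  set.seed(4)
  for (i in 1:50) {
    s <- tibble::tibble(patient_id = "x", compartment = "RN",
                        months_before_onset = NA_real_,
                        CDO1 = runif(1, 0, 3), HOPX = runif(1, 0, 2),
                        Reprimo = runif(1, 0, 1), ECAD = runif(1, 0, 0.5))
    sc <- score_samples(s, th)
    brute <- sum(c(s$CDO1 >= th["CDO1"], s$HOPX >= th["HOPX"],
                   s$Reprimo >= th["Reprimo"], s$ECAD >= th["ECAD"]))
    expect_identical(sc$total, as.integer(brute))
    s_up <- s |> dplyr::mutate(HOPX = HOPX + runif(1, 0, 5))
    expect_gte(score_samples(s_up, th)$total, sc$total)
  }
})

test_that("score distribution reports counts, percents and >= fractions", {
  scores <- rep(0:4, c(2, 6, 14, 10, 3))
  d <- score_distribution(scores, k = 4)
  expect_identical(d$n, c(2L, 6L, 14L, 10L, 3L))
  expect_equal(d$percent[d$score == 2], 40)
  expect_equal(d$pct_ge[d$score == 2], 77.1)
  expect_equal(sum(d$percent), 100, tolerance = 0.1)

  benign <- rep(0:4, c(4, 6, 7, 4, 2))
  expect_equal(score_distribution(benign, k = 4)$pct_ge[3], 56.5)

  df <- tibble::tibble(total = c(1L, 3L, 2L), complete = c(TRUE, FALSE, TRUE),
                       pt_CDO1 = 1L, pt_HOPX = 1L, pt_Reprimo = 1L,
                       pt_ECAD = 1L)
  expect_message(d2 <- score_distribution(df), regexp = "1 incomplete")
  expect_equal(sum(d2$n), 2)
  expect_error(score_distribution(df[df$complete == FALSE, ]),
               class = "methrisk_domain_error")
})

test_that("combination enumeration covers the subset x split grid", {
  set.seed(61)
  n <- 43
  total4 <- rep(0:4, c(5, 10, 14, 10, 4))   # every score level populated
  pts <- tibble::tibble(CDO1 = as.integer(total4 >= 1),
                        HOPX = as.integer(total4 >= 2),
                        Reprimo = as.integer(total4 >= 3),
                        ECAD = as.integer(total4 >= 4))
  terms <- 150 - 25 * total4 + rnorm(n, 0, 20)  # higher score, shorter term
  res <- enumerate_combinations(pts, terms)
  # 3 pairs x 3 splits + trio x 4 + all-four x 5
  expect_equal(nrow(res), 3 * 3 + 4 + 5)
  expect_setequal(unique(res$test), c("anova", "t"))
  four <- res[res$subset == "CDO1, HOPX, Reprimo, ECAD", ]
  expect_true(all(four$evaluable))
  expect_lt(four$p[four$split == "0-1 vs 2-4"], 0.05)
  gs <- four$group_stats[four$split == "0-1 vs 2-4"][[1]]
  expect_equal(sum(gs$n), n)
  expect_lt(gs$mean[2], gs$mean[1])
})

test_that("degenerate splits are not-evaluable and equal terms give p = 1", {
  pts <- tibble::tibble(CDO1 = rep(1L, 10), HOPX = rep(1L, 10),
                        Reprimo = rep(0L, 10), ECAD = rep(0L, 10))
  terms <- rnorm(10, 100, 10)
  res <- enumerate_combinations(pts, terms, subsets = list(c("CDO1", "HOPX")))
  # every sample scores exactly 2: "0 vs 1-2" has an empty low side
  expect_false(res$evaluable[res$split == "0 vs 1-2"])

  pts2 <- tibble::tibble(CDO1 = rbinom(12, 1, 0.5), HOPX = rbinom(12, 1, 0.5))
  res2 <- enumerate_combinations(pts2, rep(100, 12),
                                 subsets = list(c("CDO1", "HOPX")))
  expect_true(all(res2$p[res2$evaluable] == 1))
})
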