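# Association and comparison statistics. Pooled-variance Student t
# throughout (it reproduces the published p-values from printed group
# summaries, which Welch does not); Spearman for gene-gene correlation
# because TaqMeth V is zero-inflated and right-skewed.

#' Pooled-variance Student t-test from group summaries
#'
#' Two-sided pooled t from (n, mean, SD) pairs:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))`, df = n1 + n2 - 2.
#' Lets printed clinical-table summaries be re-tested without raw data.
#'
#' @param n1,mean1,sd1 first group's size (>= 2), mean, SD (> 0).
#' @param n2,mean2,sd2 second group's summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
student_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2",
                              class = "methrisk_domain_error")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be >= 0",
                                class = "methrisk_domain_error")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
  } else {
    (mean1 - mean2) / se
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled-variance Student t-test on raw vectors
#'
#' Identical to [student_t_from_summary()] applied to the vectors'
#' summaries (and to `t.test(var.equal = TRUE)`).
#'
#' @param x,y numeric vectors (each n >= 2; missing values dropped).
#' @return list with `t`, `df`, `p`.
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need n >= 2", class = "methrisk_domain_error")
  }
  student_t_from_summary(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
}

#' One-way ANOVA with Tukey HSD
#'
#' One-way analysis of variance across k groups (k >= 2) followed by
#' Tukey's honestly-significant-difference test on all pairs. With two
#' groups the F statistic equals the squared pooled t.
#'
#' @param groups list of numeric vectors, optionally named.
#' @return list with `F`, `df` (c(between, within)), `p`, and `tukey`,
#'   a tibble of pairwise comparisons (`pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
anova_tukey <- function(groups) {
  groups <- purrr::map(groups, ~ .x[!is.na(.x)])
  if (length(groups) < 2) abort("need at least 2 groups",
                                class = "methrisk_domain_error")
  if (any(lengths(groups) < 2)) abort("every group needs n >= 2",
                                      class = "methrisk_domain_error")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  dat <- tibble(value = unlist(groups, use.names = FALSE),
                group = factor(rep(names(groups), lengths(groups)),
                               levels = names(groups)))
  if (sd(dat$value) == 0) {
    # no variation at all: F is 0/0 by the formula; report the null result
    pairs <- utils::combn(names(groups), 2)
    return(list(F = 0, df = c(length(groups) - 1, nrow(dat) - length(groups)),
                p = 1,
                tukey = tibble(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                               diff = 0, lwr = 0, upr = 0, p_adj = 1)))
  }
  fit <- aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(F = tab[["F value"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p = tab[["Pr(>F)"]][1],
       tukey = tibble(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"]))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction, df = 1. A zero row or column margin is a
#' domain error (the statistic is undefined).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return list with `chi2`, `df`, `p`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2",
                                         class = "methrisk_domain_error")
  if (any(table < 0)) abort("counts must be non-negative",
                            class = "methrisk_domain_error")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: chi-squared undefined", class = "methrisk_domain_error")
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Simple linear regression r-squared
#'
#' Ordinary least squares of `y` on `x`: returns the coefficient of
#' determination, the sign of the slope, and the two-sided p-value for
#' slope = 0.
#'
#' @param x,y aligned numeric vectors (n >= 3; `x` non-constant).
#' @return list with `r2`, `slope_sign` (-1/0/1), `slope`, `p`.
#' @export
linear_r2 <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need n >= 3", class = "methrisk_domain_error")
  if (length(unique(x)) == 1) abort("x is constant",
                                    class = "methrisk_domain_error")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))  # "perfect fit" warning carries no info here
  slope <- unname(coef(fit)[2])
  list(r2 = s$r.squared, slope_sign = sign(slope), slope = slope,
       p = s$coefficients[2, 4])
}

#' Pairwise gene-gene Spearman correlations within a compartment
#'
#' Spearman rank correlation for every gene pair, pairwise-complete; a
#' pair with fewer than 3 complete observations is reported as missing.
#'
#' @param samples wide sample tibble.
#' @param genes genes to correlate (default: the panel).
#' @param compartment which compartment's samples to use.
#' @return tibble with `gene_a`, `gene_b`, `rho`, `p`, `n`.
#' @export
pairwise_correlation <- function(samples, genes = PANEL_GENES, compartment) {
  dat <- samples |> filter(.data$compartment == !!compartment)
  pairs <- utils::combn(genes, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    x <- dat[[pr[1]]]; y <- dat[[pr[2]]]
    keep <- complete.cases(x, y)
    n <- sum(keep)
    if (n < 3) {
      return(tibble(gene_a = pr[1], gene_b = pr[2],
                    rho = NA_real_, p = NA_real_, n = n))
    }
    ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman"))
    tibble(gene_a = pr[1], gene_b = pr[2],
           rho = unname(ct$estimate), p = ct$p.value, n = n)
  }) |> list_rbind()
}
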