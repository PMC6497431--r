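# Cut-off discovery. Three procedures, all scanning the observed unique
# values as the candidate set, with >= theta defining a positive call
# (matching the scoring rule: a value equal to the cut-off scores 1):
#   * ROC / Youden J for tumor-vs-mucosa diagnostic thresholds,
#   * minimum-p log-rank scan for survival thresholds,
#   * minimum-p pooled t-test scan for time-to-onset thresholds.
# Minimum-p selection inflates type-I error when uncorrected; an optional
# permutation adjustment is available on both scan procedures.

cutoff_result <- function(gene = NA_character_, purpose, threshold = NA_real_,
                          auc = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, scan_p = NA_real_,
                          relative_risk = NA_real_, found = FALSE,
                          scan = NULL) {
  tibble(gene = gene, purpose = purpose, threshold = threshold, auc = auc,
         sensitivity = sensitivity, specificity = specificity,
         scan_p = scan_p, relative_risk = relative_risk, found = found,
         scan = if (is.null(scan)) list(NULL) else list(scan))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The all-pairs concordance probability `P(pos > neg) + P(pos = neg)/2`,
#' computed through midranks, so ties count one half.
#'
#' @param pos scores of the positive class (e.g. tumor TaqMeth V).
#' @param neg scores of the negative class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be non-empty", class = "methrisk_domain_error")
  }
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(neg))
}

#' Youden-optimal diagnostic cut-off
#'
#' Scans every observed unique value as a candidate threshold with
#' `value >= theta` as the positive call, and returns the threshold
#' maximising Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the larger threshold (favouring specificity).
#'
#' @param pos,neg scores of the two classes.
#' @param gene optional gene label carried into the result.
#' @return one-row cut-off tibble (purpose `"DIAGNOSTIC"`) with the
#'   threshold, AUC, sensitivity and specificity, and the full candidate
#'   scan as a list-column.
#' @export
youden_cutoff <- function(pos, neg, gene = NA_character_) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be non-empty", class = "methrisk_domain_error")
  }
  cand <- sort(unique(c(pos, neg)))
  scan <- tibble(
    threshold = cand,
    sensitivity = vapply(cand, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(cand, function(t) mean(neg < t), numeric(1))
  ) |>
    mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  best <- scan |>
    filter(.data$youden_j == max(.data$youden_j)) |>
    slice_max(.data$threshold, n = 1)
  cutoff_result(gene = gene, purpose = "DIAGNOSTIC",
                threshold = best$threshold, auc = roc_auc(pos, neg),
                sensitivity = best$sensitivity, specificity = best$specificity,
                found = TRUE, scan = scan)
}

#' Percent of values at or above a threshold
#'
#' `100 * |{v : v >= theta}| / n`, reported to one decimal
#' (half away from zero).
#'
#' @param values numeric vector (missing values excluded).
#' @param threshold the cut-off.
#' @return percent in `[0, 100]`, one decimal.
#' @export
proportion_above <- function(values, threshold) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("values must be non-empty", class = "methrisk_domain_error")
  }
  round_half_away(100 * mean(values >= threshold), 1)
}

# Candidate thresholds whose >= / < split leaves both groups with at
# least ceil(min_group_frac * n) members.
eligible_candidates <- function(values, min_group_frac) {
  if (min_group_frac <= 0 || min_group_frac >= 0.5) {
    abort("min_group_frac must be in (0, 0.5)", class = "methrisk_domain_error")
  }
  n <- length(values)
  k <- ceiling(min_group_frac * n)
  cand <- sort(unique(values))
  keep <- vapply(cand, function(t) {
    hi <- sum(values >= t)
    hi >= k && (n - hi) >= k
  }, logical(1))
  cand[keep]
}

#' Minimum-p log-rank cut-off scan (survival)
#'
#' Scans observed unique values; candidates leaving either side of the
#' `>= theta` split with fewer than `ceil(min_group_frac * n)` subjects are
#' skipped. Each eligible split is tested with the two-group log-rank test;
#' the threshold with the smallest p is returned. When no eligible
#' candidate reaches `p < alpha` the result carries `found = FALSE` and no
#' threshold ("no optimal cut-off obtained"). The relative risk is the
#' univariate Cox hazard ratio of the high-methylation indicator.
#'
#' @param values marker values, aligned with `times`/`events`.
#' @param times survival times (months).
#' @param events logical event indicators.
#' @param min_group_frac minimum group fraction (default 0.1).
#' @param alpha significance level deciding `found` (default 0.05).
#' @param purpose `"SURVIVAL_OS"` or `"SURVIVAL_RFS"` (label only).
#' @param gene optional gene label.
#' @param n_perm if > 0, additionally compute a permutation-adjusted
#'   minimum-p (`scan_p_adjusted` column in the scan attribute is global).
#' @return one-row cut-off tibble with the scan as a list-column.
#' @export
minp_logrank_cutoff <- function(values, times, events, min_group_frac = 0.1,
                                alpha = 0.05, purpose = "SURVIVAL_OS",
                                gene = NA_character_, n_perm = 0) {
  keep <- complete.cases(values, times, events)
  values <- values[keep]; times <- times[keep]; events <- as.logical(events[keep])
  if (length(values) == 0 || !any(events)) {
    abort("no usable observations (all events missing)",
          class = "methrisk_domain_error")
  }
  scan_min_p <- function(v) {
    cand <- eligible_candidates(v, min_group_frac)
    if (length(cand) == 0) return(NULL)
    p <- vapply(cand, function(t) logrank_test(times[v >= t], events[v >= t],
                                               times[v < t], events[v < t])$p,
                numeric(1))
    tibble(threshold = cand, p = p)
  }
  scan <- scan_min_p(values)
  if (is.null(scan)) {
    return(cutoff_result(gene = gene, purpose = purpose, found = FALSE))
  }
  best <- scan |> filter(.data$p == min(.data$p)) |> slice_max(.data$threshold, n = 1)
  p_adj <- NA_real_
  if (n_perm > 0) {
    obs <- min(scan$p)
    perm <- vapply(seq_len(n_perm), function(i) {
      s <- scan_min_p(sample(values))
      if (is.null(s)) 1 else min(s$p)
    }, numeric(1))
    p_adj <- mean(perm <= obs)
  }
  if (best$p >= alpha) {
    res <- cutoff_result(gene = gene, purpose = purpose, scan_p = best$p,
                         found = FALSE, scan = scan)
    return(res)
  }
  hi <- as.integer(values >= best$threshold)
  # a perfectly separating split gives a monotone likelihood; the reported
  # hazard ratio is then the capped estimate, which is all the scan needs
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ hi, ties = "efron"))
  res <- cutoff_result(gene = gene, purpose = purpose, threshold = best$threshold,
                       scan_p = best$p, relative_risk = unname(exp(coef(fit)[1])),
                       found = TRUE, scan = scan)
  if (n_perm > 0) res$scan_p_adjusted <- p_adj
  res
}

#' Minimum-p t-test cut-off scan (time to onset)
#'
#' Scans observed unique values with the same eligibility rule as the
#' log-rank scan; each eligible `>= theta` split is tested with the
#' two-sided pooled-variance Student t-test on the onset terms. The
#' threshold minimising p is returned, along with both groups' n / mean /
#' SD. Sensitivity and specificity are reported descriptively against the
#' label "term at or below the cohort median" with `value >= theta` as the
#' positive call. Degenerate input (all marker values equal, or no
#' eligible candidate) yields `found = FALSE`.
#'
#' @param values marker values, aligned with `terms`.
#' @param terms months to onset.
#' @param min_group_frac minimum group fraction (default 0.1).
#' @param gene optional gene label.
#' @param n_perm if > 0, permutation-adjusted minimum-p as in
#'   [minp_logrank_cutoff()].
#' @return one-row cut-off tibble (purpose `"TERM_SPLIT"`) with group
#'   summaries (`n_short`, `mean_short`, `sd_short`, `n_long`,
#'   `mean_long`, `sd_long`) and the scan as a list-column.
#' @export
minp_ttest_cutoff <- function(values, terms, min_group_frac = 0.1,
                              gene = NA_character_, n_perm = 0) {
  keep <- complete.cases(values, terms)
  values <- values[keep]; terms <- terms[keep]
  if (length(values) < 4) {
    abort("need at least 4 aligned observations", class = "methrisk_domain_error")
  }
  if (length(unique(values)) == 1) {
    return(cutoff_result(gene = gene, purpose = "TERM_SPLIT", found = FALSE))
  }
  scan_min_p <- function(v, trm) {
    cand <- eligible_candidates(v, min_group_frac)
    cand <- cand[vapply(cand, function(t) sum(v >= t) >= 2 && sum(v < t) >= 2,
                        logical(1))]
    if (length(cand) == 0) return(NULL)
    p <- vapply(cand, function(t) student_t(trm[v >= t], trm[v < t])$p, numeric(1))
    tibble(threshold = cand, p = p)
  }
  scan <- scan_min_p(values, terms)
  if (is.null(scan)) {
    return(cutoff_result(gene = gene, purpose = "TERM_SPLIT", found = FALSE))
  }
  best <- scan |> filter(.data$p == min(.data$p)) |> slice_max(.data$threshold, n = 1)
  hi <- values >= best$threshold
  short_label <- terms <= median(terms)
  res <- cutoff_result(gene = gene, purpose = "TERM_SPLIT",
                       threshold = best$threshold, scan_p = best$p,
                       sensitivity = mean(hi[short_label]),
                       specificity = mean(!hi[!short_label]),
                       found = TRUE, scan = scan)
  res$n_short <- sum(hi); res$mean_short <- mean(terms[hi]); res$sd_short <- sd(terms[hi])
  res$n_long <- sum(!hi); res$mean_long <- mean(terms[!hi]); res$sd_long <- sd(terms[!hi])
  if (n_perm > 0) {
    obs <- min(scan$p)
    perm <- vapply(seq_len(n_perm), function(i) {
      s <- scan_min_p(values, sample(terms))
      if (is.null(s)) 1 else min(s$p)
    }, numeric(1))
    res$scan_p_adjusted <- mean(perm <= obs)
  }
  res
}

#' Per-gene diagnostic cut-offs from a sample table
#'
#' Runs [youden_cutoff()] for every requested gene with the tumor (RT)
#' compartment as the positive class and the remnant mucosa (RN) as the
#' negative class, and appends the percent of each class at or above the
#' threshold.
#'
#' @param samples wide sample tibble.
#' @param genes genes to scan (default: the whole panel).
#' @return cut-off tibble, one row per gene, with columns
#'   `pct_tumor_above` and `pct_mucosa_above`.
#' @export
find_diagnostic_cutoffs <- function(samples, genes = PANEL_GENES) {
  purrr::map(genes, function(g) {
    pos <- samples[[g]][samples$compartment == "RT"]
    neg <- samples[[g]][samples$compartment == "RN"]
    res <- youden_cutoff(pos, neg, gene = g)
    res$pct_tumor_above <- proportion_above(pos, res$threshold)
    res$pct_mucosa_above <- proportion_above(neg, res$threshold)
    res
  }) |> list_rbind()
}

#' Per-gene survival cut-offs from sample and patient tables
#'
#' Joins a compartment's marker values to the patients' OS or RFS
#' outcomes and runs the minimum-p log-rank scan per gene.
#'
#' @param samples wide sample tibble.
#' @param patients patient tibble with survival columns.
#' @param endpoint `"os"` or `"rfs"`.
#' @param genes genes to scan.
#' @param compartment compartment supplying marker values (default tumor).
#' @param min_group_frac,alpha scan controls (see [minp_logrank_cutoff()]).
#' @return cut-off tibble, one row per gene.
#' @export
find_survival_cutoffs <- function(samples, patients,
                                  endpoint = c("os", "rfs"),
                                  genes = PANEL_GENES, compartment = "RT",
                                  min_group_frac = 0.1, alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  time_col <- paste0(endpoint, "_time")
  event_col <- paste0(endpoint, "_event")
  dat <- samples |>
    filter(.data$compartment == !!compartment) |>
    inner_join(patients, by = "patient_id")
  purrr::map(genes, function(g) {
    minp_logrank_cutoff(dat[[g]], dat[[time_col]], dat[[event_col]],
                        min_group_frac = min_group_frac, alpha = alpha,
                        purpose = paste0("SURVIVAL_", toupper(endpoint)),
                        gene = g)
  }) |> list_rbind()
}

#' Per-gene time-to-onset cut-offs from a biopsy series
#'
#' Runs the minimum-p pooled t-test scan of each gene's biopsy TaqMeth V
#' against months before onset.
#'
#' @param samples wide sample tibble (BIOPSY rows are used).
#' @param genes genes to scan.
#' @param min_group_frac scan control (see [minp_ttest_cutoff()]).
#' @return cut-off tibble, one row per gene.
#' @export
find_term_cutoffs <- function(samples, genes = PANEL_GENES,
                              min_group_frac = 0.1) {
  bx <- samples |> filter(.data$compartment == "BIOPSY")
  if (nrow(bx) == 0) abort("no BIOPSY samples present",
                           class = "methrisk_domain_error")
  purrr::map(genes, function(g) {
    minp_ttest_cutoff(bx[[g]], bx$months_before_onset,
                      min_group_frac = min_group_frac, gene = g)
  }) |> list_rbind()
}
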