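# Independent oracles, kept deliberately naive: double loops and literal
# risk-table arithmetic, never the package's own code paths.

# All-pairs concordance AUC, ties counted one half.
oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exhaustive Youden scan (>= theta positive, ties to larger theta).
oracle_youden <- function(pos, neg) {
  best <- NULL
  for (t in sort(unique(c(pos, neg)))) {
    j <- mean(pos >= t) + mean(neg < t) - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && t > best$theta)) {
      best <- list(theta = t, j = j)
    }
  }
  best
}

# Literal risk-table log-rank chi-squared for two groups.
oracle_logrank_chi2 <- function(tA, eA, tB, eB) {
  tm <- c(tA, tB); ev <- c(eA, eB)
  grp <- rep(c(1, 2), c(length(tA), length(tB)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(tm[ev]))) {
    at_risk <- tm >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(ev & tm == t); d1 <- sum(ev & tm == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Brute-force minimum-p log-rank scan (uses survdiff directly as the
# per-split test, independent of the package's scan code).
oracle_minp_logrank <- function(values, times, events, frac) {
  n <- length(values); k <- ceiling(frac * n)
  best <- NULL
  for (t in sort(unique(values))) {
    hi <- values >= t
    if (sum(hi) < k || sum(!hi) < k) next
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ hi)
    p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p - 1e-12 ||
        (abs(p - best$p) <= 1e-12 && t > best$theta)) {
      best <- list(theta = t, p = p)
    }
  }
  best
}

# Brute-force minimum-p pooled-t scan using stats::t.test.
oracle_minp_ttest <- function(values, terms, frac) {
  n <- length(values); k <- ceiling(frac * n)
  best <- NULL
  for (t in sort(unique(values))) {
    hi <- values >= t
    if (sum(hi) < max(k, 2) || sum(!hi) < max(k, 2)) next
    p <- stats::t.test(terms[hi], terms[!hi], var.equal = TRUE)$p.value
    if (is.null(best) || p < best$p - 1e-12 ||
        (abs(p - best$p) <= 1e-12 && t > best$theta)) {
      best <- list(theta = t, p = p)
    }
  }
  best
}

# Standard error of the sample SD of a zero-inflated log-normal with
# overall moments (m, s) and zero mass pi0, from the analytic fourth
# central moment: SE(s_hat) ~ sqrt((mu4 - s^4)/n) / (2 s). Heavy-tailed
# cells make this large, so SD-recovery checks must budget for it.
zi_ln_se_sd <- function(m, s, pi0, n) {
  m1 <- m / (1 - pi0); ex2 <- (m^2 + s^2) / (1 - pi0)
  sig2 <- log(ex2 / m1^2); mu <- log(m1) - sig2 / 2
  raw <- function(k) (1 - pi0) * exp(k * mu + k^2 * sig2 / 2)
  mu4 <- raw(4) - 4 * m * raw(3) + 6 * m^2 * raw(2) - 3 * m^4
  sqrt((mu4 - s^4) / n) / (2 * s)
}

# Closed-form mean of a normal truncated below at `lower`.
truncnorm_mean <- function(mean, sd, lower) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Tiny valid patient table used across IO tests.
make_patients <- function(n = 3) {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    initial_diagnosis = rep(c("MALIGNANT", "BENIGN"), length.out = n),
    age = 60 + seq_len(n),
    sex = rep(c("M", "F"), length.out = n),
    term_to_rgc = c(120.5, 360.25, 48)[seq_len(n)],
    hp_status = rep("UNKNOWN", n),
    reconstruction = rep("BI", n),
    site = rep("ANASTOMOTIC", n),
    depth_T = rep("SM_OR_LESS", n),
    node_N = rep("NEG", n),
    metastasis_M = rep("NEG", n),
    stage = rep("II", n),
    ly = rep("NEG", n),
    v = rep("NEG", n),
    inf_pattern = rep("b", n),
    lauren = rep("INTESTINAL", n),
    os_time = c(60, 24.5, 60)[seq_len(n)],
    os_event = c(FALSE, TRUE, FALSE)[seq_len(n)],
    rfs_time = c(60, 12.25, 60)[seq_len(n)],
    rfs_event = c(FALSE, TRUE, FALSE)[seq_len(n)]
  )
}

make_measurements_long <- function() {
  tibble::tibble(
    patient_id = "P01",
    compartment = "RT",
    gene = c("CDO1", "HOPX", "Reprimo", "ECAD"),
    taqmeth_v = c(16.9, 10.1, 0, 0.26),
    months_before_onset = NA_real_
  )
}
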