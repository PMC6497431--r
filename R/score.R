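# The methylation risk score: one point per gene at or above its
# cut-off, summed over the scored panel (0..4 with all four genes).

#' Score a single gene value against its cut-off
#'
#' 1 point iff `value >= threshold`; values below score 0. A missing
#' value propagates as `NA` (never scored 0: absence of the assay is not
#' absence of methylation). Vectorised.
#'
#' @param value TaqMeth V (>= 0, `NA` allowed).
#' @param threshold the gene's cut-off (> 0).
#' @return integer 0/1 (or `NA`).
#' @export
gene_point <- function(value, threshold) {
  if (any(is.na(threshold)) || any(threshold <= 0)) {
    abort("threshold must be > 0", class = "methrisk_domain_error")
  }
  if (any(!is.na(value) & value < 0)) {
    abort("value must be >= 0", class = "methrisk_domain_error")
  }
  as.integer(value >= threshold)
}

# Normalise a cut-off spec (named vector, or tibble with gene/threshold)
# into a named numeric vector over `genes`.
cutoff_vector <- function(cutoffs, genes) {
  if (is.data.frame(cutoffs)) {
    cutoffs <- setNames(cutoffs$threshold, cutoffs$gene)
  }
  missing_genes <- setdiff(genes, names(cutoffs))
  if (length(missing_genes) > 0) {
    abort(paste0("no cut-off supplied for gene(s): ",
                 paste(missing_genes, collapse = ", ")),
          class = "methrisk_config_error")
  }
  cutoffs[genes]
}

#' Compute risk scores for a sample table
#'
#' Applies [gene_point()] per gene over the requested subset and sums.
#' The `complete` flag marks samples with every subset gene measured;
#' for incomplete samples `total` is a lower bound (missing genes
#' contribute nothing but are never imputed 0).
#'
#' @param samples wide sample tibble.
#' @param cutoffs named vector `gene -> threshold`, or a cut-off tibble
#'   with `gene` and `threshold` columns.
#' @param genes gene subset to score (default: the whole panel).
#' @return `samples`'s id columns plus per-gene point columns
#'   (`pt_<gene>`), `total`, and `complete`.
#' @export
score_samples <- function(samples, cutoffs, genes = PANEL_GENES) {
  unknown <- setdiff(genes, PANEL_GENES)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene(s) in subset: ", paste(unknown, collapse = ", ")),
          class = "methrisk_config_error")
  }
  th <- cutoff_vector(cutoffs, genes)
  out <- samples |>
    select(any_of(c("patient_id", "compartment", "months_before_onset")))
  for (g in genes) out[[paste0("pt_", g)]] <- gene_point(samples[[g]], th[[g]])
  pts <- as.matrix(out[, paste0("pt_", genes), drop = FALSE])
  out$total <- as.integer(rowSums(pts, na.rm = TRUE))
  out$complete <- !apply(pts, 1, anyNA)
  out
}

#' Score distribution with cumulative fractions
#'
#' Counts per score 0..k, percents to one decimal (half away from zero),
#' and the "score >= s" count and percent for every s. Incomplete scores
#' (some subset gene unmeasured) are excluded with a message saying how
#' many.
#'
#' @param scores a tibble from [score_samples()] (columns `total`,
#'   `complete`) or a bare integer vector of complete scores.
#' @param k maximum attainable score (default: number of scored genes
#'   inferred from the data, or `max(scores)`).
#' @return tibble with `score`, `n`, `percent`, `n_ge`, `pct_ge`.
#' @export
score_distribution <- function(scores, k = NULL) {
  if (is.data.frame(scores)) {
    n_excluded <- sum(!scores$complete)
    if (n_excluded > 0) {
      inform(sprintf("excluding %d incomplete score(s) from the distribution",
                     n_excluded))
    }
    if (is.null(k)) {
      pt_cols <- grep("^pt_", names(scores), value = TRUE)
      if (length(pt_cols) > 0) k <- length(pt_cols)
    }
    scores <- scores$total[scores$complete]
  }
  if (length(scores) == 0) {
    abort("no complete scores to summarise", class = "methrisk_domain_error")
  }
  if (is.null(k)) k <- max(scores)
  stopifnot(all(scores >= 0), all(scores <= k))
  n_total <- length(scores)
  tibble(score = 0:k) |>
    mutate(n = vapply(.data$score, function(s) sum(scores == s), integer(1)),
           percent = round_half_away(100 * .data$n / n_total, 1),
           n_ge = vapply(.data$score, function(s) sum(scores >= s), integer(1)),
           pct_ge = round_half_away(100 * .data$n_ge / n_total, 1))
}

# Binary and all-level splits of a 0..k score, in table layout order:
# "0,1,...,k" (ANOVA) then "0 vs 1-k", "0-1 vs 2-k", ..., "0-(k-1) vs k".
score_splits <- function(k) {
  fmt_range <- function(lo, hi) if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  splits <- list(list(label = paste(0:k, collapse = ","), cut = NA_integer_))
  for (j in 0:(k - 1)) {
    splits <- c(splits, list(list(
      label = paste0(fmt_range(0, j), " vs ", fmt_range(j + 1, k)),
      cut = j
    )))
  }
  splits
}

#' Enumerate gene-subset score splits against the time to onset
#'
#' For each gene subset (by default every pair of the CDO1/HOPX/Reprimo
#' trio, the trio itself, and all four genes) and each split of its 0..k
#' score — the all-levels comparison and every binary cut — tests the
#' onset terms: binary splits with the pooled Student t-test, multi-level
#' rows with one-way ANOVA. Samples missing any gene of a subset are
#' excluded from that subset's rows. A split leaving a side (or a level
#' structure) degenerate is reported as not evaluable rather than erroring.
#'
#' @param points tibble of per-gene 0/1 points (columns named by gene —
#'   e.g. the `pt_*` columns of [score_samples()] renamed, or raw 0/1
#'   columns) aligned with `terms`.
#' @param terms months to onset, aligned with `points` rows.
#' @param subsets list of character vectors of gene names (default as
#'   described above).
#' @return tibble with `subset`, `split`, `test`, `p`, `evaluable`, and a
#'   `group_stats` list-column of per-group n / mean / SD.
#' @export
enumerate_combinations <- function(points, terms, subsets = NULL) {
  names(points) <- sub("^pt_", "", names(points))
  if (is.null(subsets)) {
    trio <- c("CDO1", "HOPX", "Reprimo")
    subsets <- c(utils::combn(trio, 2, simplify = FALSE), list(trio),
                 list(PANEL_GENES))
  }
  if (length(terms) != nrow(points)) {
    abort("terms must align with points rows", class = "methrisk_domain_error")
  }
  rows <- list()
  for (sub_genes in subsets) {
    missing_genes <- setdiff(sub_genes, names(points))
    if (length(missing_genes) > 0) {
      abort(paste0("points table lacks gene(s): ",
                   paste(missing_genes, collapse = ", ")),
            class = "methrisk_config_error")
    }
    pts <- as.matrix(points[, sub_genes, drop = FALSE])
    keep <- !apply(pts, 1, anyNA) & !is.na(terms)
    total <- rowSums(pts[keep, , drop = FALSE])
    trm <- terms[keep]
    k <- length(sub_genes)
    subset_label <- paste(sub_genes, collapse = ", ")
    for (sp in score_splits(k)) {
      row <- tibble(subset = subset_label, split = sp$label,
                    test = NA_character_, p = NA_real_, evaluable = FALSE,
                    group_stats = list(NULL))
      if (is.na(sp$cut)) {
        groups <- split(trm, factor(total, levels = 0:k))
        groups <- groups[lengths(groups) > 0]
        row$test <- "anova"
        if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
          gs <- tibble(group = names(groups), n = lengths(groups),
                       mean = vapply(groups, mean, numeric(1)),
                       sd = vapply(groups, sd, numeric(1)))
          row$group_stats <- list(gs)
          if (sd(trm) == 0) {
            row$p <- 1; row$evaluable <- TRUE
          } else {
            row$p <- anova_tukey(groups)$p
            row$evaluable <- TRUE
          }
        }
      } else {
        lo <- trm[total <= sp$cut]
        hi <- trm[total > sp$cut]
        row$test <- "t"
        if (length(lo) >= 2 && length(hi) >= 2) {
          row$group_stats <- list(tibble(
            group = strsplit(sp$label, " vs ")[[1]],
            n = c(length(lo), length(hi)),
            mean = c(mean(lo), mean(hi)),
            sd = c(sd(lo), sd(hi))))
          row$p <- student_t(lo, hi)$p
          row$evaluable <- TRUE
        }
      }
      rows <- c(rows, list(row))
    }
  }
  list_rbind(rows)
}
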