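# Quick-look plots. Tables are the primary output; these are ggplot2
# conveniences for the main result types.

#' @export
autoplot.rgc_km <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1),
                  tibble(time = object$time, surv = object$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rgc_propensity <- function(object, ...) {
  thr <- sort(unique(c(0, object$scores, 1)), decreasing = TRUE)
  roc <- tibble(
    fpr = vapply(thr, function(t) mean(object$scores[!object$labels] >= t),
                 numeric(1)),
    tpr = vapply(thr, function(t) mean(object$scores[object$labels] >= t),
                 numeric(1))
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("In-sample AUC = %.2f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a cut-off scan
#'
#' For a diagnostic cut-off, Youden's J across candidate thresholds; for
#' the minimum-p scans, -log10 p. The selected threshold is marked.
#'
#' @param cutoff one row of a cut-off tibble (with its `scan` list-column).
#' @return a ggplot.
#' @export
plot_cutoff_scan <- function(cutoff) {
  scan <- cutoff$scan[[1]]
  if (is.null(scan)) abort("no scan recorded for this cut-off")
  if ("youden_j" %in% names(scan)) {
    p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$threshold,
                                            y = .data$youden_j)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = "Youden J")
  } else {
    p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$threshold,
                                            y = -log10(.data$p))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = "-log10 p")
  }
  if (isTRUE(cutoff$found)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff$threshold,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = "Candidate threshold TaqMeth V",
                    title = cutoff$gene %||% "") +
    ggplot2::theme_minimal()
}

#' Plot onset terms by risk-score group
#'
#' @param scores tibble from [score_samples()] (needs `total`,
#'   `complete`).
#' @param terms months to onset aligned with `scores` rows.
#' @return a ggplot (boxplot of terms per score).
#' @export
plot_score_terms <- function(scores, terms) {
  df <- tibble(score = factor(scores$total), term = terms,
               complete = scores$complete) |>
    filter(.data$complete, !is.na(.data$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$term)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "Methylation score", y = "Months to onset") +
    ggplot2::theme_minimal()
}
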