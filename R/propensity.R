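# Logistic propensity model for the initial diagnosis (malignant vs
# benign) from remnant-mucosa methylation, optionally with age, sex and
# the term to onset. The published use is purely as a discrimination
# summary (in-sample AUC), so the apparent AUC is primary and a
# cross-validated AUC is available as honesty output.

#' Fit the initial-diagnosis propensity model
#'
#' Unregularised maximum-likelihood logistic regression of the binary
#' initial diagnosis on the supplied covariates. Propensity scores are the
#' fitted probabilities; discrimination is the in-sample AUC of the scores
#' ([roc_auc()]). Complete separation / non-convergence is detected and
#' flagged (scores are reported from the iteration-capped fit, not
#' silently penalised). Optionally reports a k-fold cross-validated AUC.
#'
#' @param data data frame holding covariates and the label.
#' @param covariates character vector of covariate column names; character
#'   columns are converted to factors, logicals to 0/1.
#' @param label_col name of the label column; either logical/0-1 or the
#'   `initial_diagnosis` labels (`"MALIGNANT"` is the positive class).
#' @param cv_folds if > 0, also compute a `cv_folds`-fold cross-validated
#'   AUC (deterministic fold assignment by row order).
#' @return object of class `"rgc_propensity"` with `coefficients`,
#'   `scores`, `labels`, `auc`, `auc_cv`, `compare_p` (pooled-t between
#'   classes), `converged` and `separation`.
#' @export
fit_propensity <- function(data, covariates,
                           label_col = "initial_diagnosis", cv_folds = 0) {
  y <- data[[label_col]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "MALIGNANT"
  y <- as.numeric(y)
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("labels must contain both classes", class = "methrisk_domain_error")
  }
  X <- as.data.frame(data[, covariates, drop = FALSE])
  for (col in names(X)) {
    if (is.character(X[[col]])) X[[col]] <- factor(X[[col]])
    if (is.logical(X[[col]])) X[[col]] <- as.numeric(X[[col]])
  }
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) <= ncol(X)) {
    abort("need more observations than covariates",
          class = "methrisk_domain_error")
  }
  dat <- cbind(data.frame(.y = y), X)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", covariates),
                                               collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = dat, family = binomial()),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }
  )
  scores <- unname(fit$fitted.values)
  eps <- 1e-8
  separation <- warned && (any(scores > 1 - eps) || any(scores < eps))
  auc <- roc_auc(scores[y == 1], scores[y == 0])

  auc_cv <- NA_real_
  if (cv_folds > 0) {
    fold <- rep_len(seq_len(cv_folds), nrow(dat))
    pred <- numeric(nrow(dat))
    for (f in seq_len(cv_folds)) {
      fit_f <- suppressWarnings(glm(fml, data = dat[fold != f, , drop = FALSE],
                                    family = binomial()))
      pred[fold == f] <- suppressWarnings(
        predict(fit_f, newdata = dat[fold == f, , drop = FALSE],
                type = "response"))
    }
    auc_cv <- roc_auc(pred[y == 1], pred[y == 0])
  }

  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                          std_error = sm[, "Std. Error"],
                          p = sm[, "Pr(>|z|)"]),
    scores = scores, labels = y == 1, auc = auc, auc_cv = auc_cv,
    compare_p = compare_scores(scores, y == 1),
    converged = fit$converged && !warned, separation = separation,
    n = nrow(dat), covariates = covariates, fit = fit
  ), class = "rgc_propensity")
}

#' In-sample AUC of the clinical propensity model over simulated cohorts
#'
#' Simulates `n_reps` study-sized cohorts (default generator conditions:
#' 35 malignant / 23 benign, truncated-normal onset terms, pooled
#' remnant-mucosa methylation for both groups), fits the 7-covariate
#' logistic model (4 RN gene values, age, sex, term to onset) on each, and
#' returns the in-sample AUCs.
#'
#' @param n_reps number of simulated cohorts.
#' @param seed base seed; cohort i uses `seed + i - 1`.
#' @param covariates model covariates (default: the 7 published ones).
#' @param config_args extra arguments passed to [generator_config()].
#' @return numeric vector of `n_reps` in-sample AUCs.
#' @export
simulate_propensity_aucs <- function(n_reps = 200, seed = 1,
                                     covariates = c(PANEL_GENES, "age", "sex",
                                                    "term_to_rgc"),
                                     config_args = list()) {
  vapply(seq_len(n_reps), function(i) {
    cfg <- do.call(generator_config, c(list(seed = seed + i - 1), config_args))
    co <- generate_cohort(cfg)
    rn <- co$samples |>
      filter(.data$compartment == "RN") |>
      inner_join(co$patients, by = "patient_id")
    fit_propensity(rn, covariates)$auc
  }, numeric(1))
}

#' Compare propensity scores between the two diagnosis classes
#'
#' Two-sided pooled-variance Student t-test of the scores between
#' classes. Degenerate scores (all equal) give `p = 1` with a warning.
#'
#' @param scores fitted propensity scores.
#' @param labels logical class labels (TRUE = positive class).
#' @return two-sided p-value.
#' @export
compare_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    abort("both classes must be present", class = "methrisk_domain_error")
  }
  if (length(unique(scores)) == 1) {
    warn("degenerate scores (all equal); p = 1")
    return(1)
  }
  student_t(scores[labels], scores[!labels])$p
}

#' @export
print.rgc_propensity <- function(x, ...) {
  cat(sprintf("Propensity model (%d covariates, n = %d): in-sample AUC %.3f",
              length(x$covariates), x$n, x$auc))
  if (!is.na(x$auc_cv)) cat(sprintf(" (cross-validated %.3f)", x$auc_cv))
  if (x$separation) cat(" [FLAGGED: separation]")
  cat("\n")
  invisible(x)
}

#' Tidy a propensity fit
#' @param x an `rgc_propensity`.
#' @param ... unused.
#' @return coefficient tibble (`term`, `estimate`, `std_error`, `p`).
#' @export
tidy.rgc_propensity <- function(x, ...) x$coefficients

#' One-row summary of a propensity fit
#' @param x an `rgc_propensity`.
#' @param ... unused.
#' @return tibble with `n`, `auc`, `auc_cv`, `compare_p`, `converged`,
#'   `separation`.
#' @export
glance.rgc_propensity <- function(x, ...) {
  tibble(n = x$n, auc = x$auc, auc_cv = x$auc_cv, compare_p = x$compare_p,
         converged = x$converged, separation = x$separation)
}
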