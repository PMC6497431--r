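# Survival machinery: Kaplan-Meier, log-rank, Cox (Efron ties), and the
# univariate-screen -> multivariate prognostic workflow in which the
# individual T/N/M components are excluded whenever composite stage enters.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. Censored subjects leave the risk set without a
#' step. Returned as a tidy tibble so curves pipe straight into ggplot2.
#'
#' @param times survival times (months, >= 0).
#' @param events logical event indicators.
#' @return tibble of class `"rgc_km"` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
kaplan_meier <- function(times, events) {
  if (any(is.na(times)) || any(times < 0)) {
    abort("times must be non-negative and non-missing",
          class = "methrisk_domain_error")
  }
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, surv = fit$surv)
  class(out) <- c("rgc_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared with 1 df. When the pooled data contain
#' no events the test carries no information; `p = 1` is returned with a
#' warning rather than an error.
#'
#' @param times_a,events_a first group.
#' @param times_b,events_b second group.
#' @return list with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("both groups must be non-empty", class = "methrisk_domain_error")
  }
  ev <- c(as.logical(events_a), as.logical(events_b))
  if (!any(ev)) {
    warn("no events in either group; log-rank p = 1")
    return(list(chi2 = 0, df = 1, p = 1))
  }
  tm <- c(times_a, times_b)
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- tryCatch(survival::survdiff(survival::Surv(tm, ev) ~ grp),
                  error = function(e) NULL)
  # a degenerate risk table (e.g. every event at one shared time) has zero
  # log-rank variance: the split carries no information
  if (is.null(sd_) || !is.finite(sd_$chisq)) {
    return(list(chi2 = 0, df = 1, p = 1))
  }
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, df = 1, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with Efron tie handling. Hazard ratios
#' with Wald 95% confidence intervals and p-values. Constant covariates
#' are rejected; non-convergence or (near-)monotone-likelihood separation
#' is flagged on the returned object, never silently dropped.
#'
#' @param times,events outcome vectors.
#' @param covariates data frame of covariates (numeric or factor).
#' @return object of class `"rgc_coxfit"`; see [tidy.rgc_coxfit()] and
#'   [glance.rgc_coxfit()].
#' @export
cox_fit <- function(times, events, covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0) abort("at least one covariate required",
                                   class = "methrisk_domain_error")
  constant <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) < 2,
                     logical(1))
  if (any(constant)) {
    abort(paste0("constant covariate(s): ",
                 paste(names(covariates)[constant], collapse = ", ")),
          class = "methrisk_domain_error")
  }
  if (sum(events) < ncol(covariates)) {
    warn("fewer events than covariates; estimates unreliable")
  }
  dat <- cbind(data.frame(.time = times, .event = as.logical(events)),
               covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  converged <- is.null(fit$info) || !warned
  separation <- warned || any(abs(coef(fit)) > 15)
  res <- tibble(term = rownames(s$coefficients),
                hr = s$coefficients[, "exp(coef)"],
                ci_low = s$conf.int[, "lower .95"],
                ci_high = s$conf.int[, "upper .95"],
                p = s$coefficients[, "Pr(>|z|)"])
  structure(list(coefficients = res, fit = fit, n = fit$n,
                 n_events = fit$nevent,
                 converged = !warned, separation = separation),
            class = "rgc_coxfit")
}

#' @export
print.rgc_coxfit <- function(x, ...) {
  cat(sprintf("Cox model: %d subjects, %d events%s\n", x$n, x$n_events,
              if (!x$converged) " [FLAGGED: convergence/separation]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a Cox fit
#' @param x an `rgc_coxfit`.
#' @param ... unused.
#' @return tibble with `term`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
tidy.rgc_coxfit <- function(x, ...) x$coefficients

#' One-row summary of a Cox fit
#' @param x an `rgc_coxfit`.
#' @param ... unused.
#' @return tibble with `n`, `n_events`, `converged`, `separation`,
#'   `concordance`.
#' @export
glance.rgc_coxfit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, converged = x$converged,
         separation = x$separation,
         concordance = unname(summary(x$fit)$concordance[1]))
}

#' Univariate-screen / multivariate Cox prognostic workflow
#'
#' Screens each declared factor univariately at `p < alpha`: categorical
#' factors by the log-rank test across levels, continuous covariates by a
#' univariate Cox Wald test. Screen survivors enter a multivariate Cox
#' model, except that the individual T/N/M components are excluded
#' whenever the composite stage also passed the screen (they are
#' constituents of stage, not independent factors). When nothing passes
#' the screen the report alone is returned.
#'
#' @param data data frame with outcomes and factors.
#' @param time_col,event_col outcome column names.
#' @param categorical character vector of categorical factor columns.
#' @param continuous character vector of continuous covariate columns.
#' @param stage_col name of the composite stage column (in `categorical`).
#' @param tnm_cols names of the T/N/M component columns.
#' @param alpha univariate screen level.
#' @return object of class `"rgc_prognosis"`: list with `screen`
#'   (per-factor univariate p and decision trace) and `multivariate`
#'   (an `rgc_coxfit`, or `NULL`).
#' @export
prognostic_workflow <- function(data, time_col, event_col,
                                categorical = character(),
                                continuous = character(),
                                stage_col = "stage",
                                tnm_cols = c("depth_T", "node_N", "metastasis_M"),
                                alpha = 0.05) {
  times <- data[[time_col]]
  events <- as.logical(data[[event_col]])
  screen_one <- function(col, type) {
    x <- data[[col]]
    keep <- !is.na(x) & x != "UNKNOWN" & !is.na(times) & !is.na(events)
    if (type == "categorical") {
      lv <- unique(x[keep])
      if (length(lv) < 2) return(NA_real_)
      sd_ <- survival::survdiff(
        survival::Surv(times[keep], events[keep]) ~ factor(x[keep]))
      pchisq(unname(sd_$chisq), df = length(lv) - 1, lower.tail = FALSE)
    } else {
      fit <- cox_fit(times[keep], events[keep],
                     setNames(data.frame(as.numeric(x[keep])), col))
      fit$coefficients$p[1]
    }
  }
  screen <- bind_rows(
    purrr::map(categorical,
               ~ tibble(factor = .x, type = "categorical",
                        p = screen_one(.x, "categorical"))),
    purrr::map(continuous,
               ~ tibble(factor = .x, type = "continuous",
                        p = screen_one(.x, "continuous")))
  ) |>
    mutate(significant = !is.na(.data$p) & .data$p < alpha)

  stage_in <- stage_col %in% screen$factor[screen$significant]
  screen <- screen |>
    mutate(excluded_tnm = .data$significant & stage_in &
             .data$factor %in% tnm_cols,
           enters_multivariate = .data$significant & !.data$excluded_tnm)

  selected <- screen$factor[screen$enters_multivariate]
  multivariate <- NULL
  if (length(selected) > 0) {
    covs <- data[, selected, drop = FALSE]
    for (col in intersect(selected, categorical)) {
      covs[[col]][covs[[col]] == "UNKNOWN"] <- NA
      covs[[col]] <- factor(covs[[col]])
    }
    for (col in intersect(selected, continuous)) {
      covs[[col]] <- as.numeric(covs[[col]])
    }
    keep <- complete.cases(covs) & !is.na(times) & !is.na(events)
    multivariate <- cox_fit(times[keep], events[keep],
                            covs[keep, , drop = FALSE])
  }
  structure(list(screen = screen, multivariate = multivariate,
                 endpoint = time_col, alpha = alpha),
            class = "rgc_prognosis")
}

#' @export
print.rgc_prognosis <- function(x, ...) {
  cat("Prognostic workflow (", x$endpoint, "), univariate screen at p < ",
      x$alpha, ":\n", sep = "")
  print(x$screen)
  if (is.null(x$multivariate)) {
    cat("No factor passed the screen; no multivariate model fitted.\n")
  } else {
    print(x$multivariate)
  }
  invisible(x)
}

#' Tidy a prognostic workflow
#' @param x an `rgc_prognosis`.
#' @param ... unused.
#' @return the multivariate coefficient tibble joined onto the screen.
#' @export
tidy.rgc_prognosis <- function(x, ...) {
  out <- x$screen
  if (!is.null(x$multivariate)) {
    mv <- tidy(x$multivariate) |>
      rename(mv_hr = "hr", mv_p = "p") |>
      mutate(factor = sub("([A-Za-z_]+).*", "\\1", .data$term)) |>
      select(all_of(c("factor", "term", "mv_hr", "mv_p")))
    out <- left_join(out, mv, by = "factor")
  }
  out
}
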