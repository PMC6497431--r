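# End-to-end orchestration: simulate (or load) -> cut-offs -> scores ->
# associations -> survival -> propensity, with TSV stage outputs and a
# JSON manifest of digests so a run is reproducible and auditable.

#' Published per-gene cut-off values
#'
#' The diagnostic (tumor vs remnant mucosa) and time-to-onset thresholds
#' reported for the panel, for injection via `cutoff_overrides` so the
#' scoring system can be applied without re-discovery.
#'
#' @return named list of named vectors: `diagnostic` and `term`.
#' @export
reference_cutoffs <- function() {
  list(
    diagnostic = c(CDO1 = 6.49, HOPX = 4.14, Reprimo = 2.59, ECAD = 1.09),
    term = c(CDO1 = 1.2, HOPX = 0.60, Reprimo = 0.15, ECAD = 0.07)
  )
}

pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    if (isTRUE(sim)) sim <- list()
    sim$seed <- sim$seed %||% cfg$seed
    gcfg <- do.call(generator_config, sim)
    cohort <- generate_cohort(gcfg)
    biopsies <- generate_biopsy_series(cohort$patients, gcfg)
    list(patients = cohort$patients,
         samples = bind_rows(cohort$samples, biopsies))
  } else {
    if (is.null(cfg$paths$patients) || is.null(cfg$paths$measurements)) {
      abort("config needs either a simulate block or paths$patients and paths$measurements",
            class = "methrisk_config_error")
    }
    list(patients = read_patients(cfg$paths$patients),
         samples = read_measurements(cfg$paths$measurements))
  }
}

override_or_scan <- function(overrides, purpose, scan_fun, genes) {
  ov <- overrides[[purpose]]
  if (!is.null(ov)) {
    label <- c(diagnostic = "DIAGNOSTIC", os = "SURVIVAL_OS",
               rfs = "SURVIVAL_RFS", term = "TERM_SPLIT")[[purpose]]
    return(list_rbind(purrr::map(genes, function(g) {
      cutoff_result(gene = g, purpose = label,
                    threshold = unname(ov[[g]]), found = TRUE)
    })))
  }
  scan_fun(genes)
}

#' Run the full methylation-risk pipeline
#'
#' Orchestrates every stage on simulated or user-supplied tables:
#' per-gene diagnostic, survival (OS/RFS) and time-to-onset cut-offs
#' (honouring `cutoff_overrides`), remnant-mucosa risk scores with the
#' score distribution by initial diagnosis, biopsy score/term split
#' enumeration, gene-gene correlations per compartment, the four-way
#' mucosa ANOVA, the prognostic Cox workflow for both endpoints, and the
#' two propensity models (methylation-only and methylation + clinical).
#' Writes one TSV per stage plus `manifest.json` (config hash, seed,
#' package version, per-file MD5 digests, methodological warnings).
#'
#' @param config a run-config list (see [read_run_config()]) or a path to
#'   a YAML config file.
#' @param out_dir output directory for report tables and the manifest.
#' @return invisibly, a list of class `"rgc_run"` with every stage result
#'   and the manifest.
#' @export
run_full <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  genes <- cfg$genes
  warnings_log <- character(0)
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    inform(paste0("[methrisk] ", msg))
  }

  inform("[methrisk] stage 1/6: inputs")
  inp <- pipeline_inputs(cfg)
  patients <- inp$patients
  samples <- inp$samples

  inform("[methrisk] stage 2/6: cut-off discovery")
  ov <- cfg$cutoff_overrides
  has_rt_rn <- all(c("RT", "RN") %in% samples$compartment)
  cut_diag <- if (has_rt_rn || !is.null(ov$diagnostic)) {
    override_or_scan(ov, "diagnostic",
                     function(g) find_diagnostic_cutoffs(samples, g), genes)
  }
  cut_os <- if ("RT" %in% samples$compartment || !is.null(ov$os)) {
    override_or_scan(ov, "os", function(g)
      find_survival_cutoffs(samples, patients, "os", g,
                            min_group_frac = cfg$min_group_frac,
                            alpha = cfg$alpha), genes)
  }
  cut_rfs <- if ("RT" %in% samples$compartment || !is.null(ov$rfs)) {
    override_or_scan(ov, "rfs", function(g)
      find_survival_cutoffs(samples, patients, "rfs", g,
                            min_group_frac = cfg$min_group_frac,
                            alpha = cfg$alpha), genes)
  }
  has_biopsy <- "BIOPSY" %in% samples$compartment
  cut_term <- if (has_biopsy || !is.null(ov$term)) {
    override_or_scan(ov, "term", function(g)
      find_term_cutoffs(samples, g, min_group_frac = cfg$min_group_frac),
      genes)
  }
  if (any(is.null(ov$os) && !is.null(cut_os), is.null(ov$term) && !is.null(cut_term))) {
    note("minimum-p cut-point scans performed without multiplicity correction; selected p-values are anti-conservative")
  }
  cutoffs <- bind_rows(cut_diag, cut_os, cut_rfs, cut_term)

  inform("[methrisk] stage 3/6: risk scores")
  scores_rn <- NULL; score_dist <- NULL; splits <- NULL; scores_biopsy <- NULL
  genes_scored <- if (is.null(cut_term)) character(0) else cut_term$gene[cut_term$found]
  if (length(genes_scored) >= 2) {
    term_th <- setNames(cut_term$threshold[cut_term$found], genes_scored)
    rn <- samples |> filter(.data$compartment == "RN")
    if (nrow(rn) > 0) {
      scores_rn <- score_samples(rn, term_th, genes_scored) |>
        left_join(patients |> select(all_of(c("patient_id", "initial_diagnosis"))),
                  by = "patient_id")
      score_dist <- scores_rn |>
        group_by(.data$initial_diagnosis) |>
        group_modify(~ score_distribution(.x, k = length(genes_scored))) |>
        ungroup()
    }
    if (has_biopsy) {
      bx <- samples |> filter(.data$compartment == "BIOPSY")
      scores_biopsy <- score_samples(bx, term_th, genes_scored)
      pts <- scores_biopsy |> select(starts_with("pt_"))
      trio <- c("CDO1", "HOPX", "Reprimo")
      subsets <- c(utils::combn(trio, 2, simplify = FALSE), list(trio),
                   list(PANEL_GENES))
      subsets <- purrr::keep(subsets, ~ all(.x %in% genes_scored))
      if (length(subsets) > 0) {
        splits <- enumerate_combinations(pts, bx$months_before_onset, subsets)
      }
    }
  }

  inform("[methrisk] stage 4/6: associations")
  correlations <- list_rbind(purrr::map(
    intersect(unique(samples$compartment), c("RT", "RN", "IN", "BIOPSY")),
    function(cp) pairwise_correlation(samples, genes, cp) |>
      mutate(compartment = cp, .before = 1)))
  anova_tbl <- mucosa_anova(samples, patients, genes)

  inform("[methrisk] stage 5/6: prognostic survival analysis")
  surv_data <- build_prognostic_table(samples, patients,
                                      list(os = cut_os, rfs = cut_rfs))
  prognosis <- purrr::map(c(os = "os", rfs = "rfs"), function(ep) {
    prognostic_workflow(surv_data, paste0(ep, "_time"), paste0(ep, "_event"),
                        categorical = attr(surv_data, "categorical"),
                        continuous = character(), alpha = cfg$alpha)
  })
  screen_tbl <- list_rbind(imap(prognosis, ~ mutate(.x$screen, endpoint = .y,
                                                    .before = 1)))
  mv_tbl <- list_rbind(imap(prognosis, function(pr, ep) {
    if (is.null(pr$multivariate)) return(NULL)
    tidy(pr$multivariate) |> mutate(endpoint = ep, .before = 1)
  }))

  inform("[methrisk] stage 6/6: propensity models")
  note("propensity AUCs are in-sample (apparent); cross-validated AUCs reported alongside")
  rn_wide <- samples |>
    filter(.data$compartment == "RN") |>
    inner_join(patients, by = "patient_id")
  prop_genes <- fit_propensity(rn_wide, genes, cv_folds = 10)
  prop_full <- fit_propensity(rn_wide, c(genes, "age", "sex", "term_to_rgc"),
                              cv_folds = 10)
  propensity_tbl <- bind_rows(
    glance(prop_genes) |> mutate(model = "genes", .before = 1),
    glance(prop_full) |> mutate(model = "genes+clinical", .before = 1))

  results <- list(
    cutoffs = cutoffs |> select(-any_of("scan")),
    scores = scores_rn %||% tibble(),
    score_distribution = score_dist %||% tibble(),
    splits = if (is.null(splits)) tibble() else splits |> select(-any_of("group_stats")),
    correlations = correlations,
    anova = anova_tbl,
    survival_screen = screen_tbl,
    survival_multivariate = mv_tbl %||% tibble(),
    propensity = propensity_tbl
  )
  paths <- write_report_tables(results, out_dir)

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "simulate_env")],
                               auto_unbox = TRUE, force = TRUE, digits = NA)
  manifest <- list(
    package = "methrisk",
    version = as.character(utils::packageVersion("methrisk")),
    seed = cfg$seed,
    config_hash = digest_string(as.character(cfg_json)),
    files = as.list(setNames(unname(tools::md5sum(paths)), basename(paths))),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(c(results,
                        list(manifest = manifest, patients = patients,
                             samples = samples,
                             propensity_fits = list(genes = prop_genes,
                                                    full = prop_full),
                             prognosis = prognosis)),
                      class = "rgc_run"))
}

digest_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

# ANOVA of each gene across the four non-cancerous mucosa cells
# (RN of initially-malignant, RN of initially-benign, IN-IM, IN-IB).
mucosa_anova <- function(samples, patients, genes) {
  dat <- samples |>
    filter(.data$compartment %in% c("RN", "IN")) |>
    inner_join(patients |> select(all_of(c("patient_id", "initial_diagnosis"))),
               by = "patient_id") |>
    mutate(cell = paste0(.data$compartment, "_",
                         ifelse(.data$initial_diagnosis == "MALIGNANT",
                                "IM", "IB")))
  list_rbind(purrr::map(genes, function(g) {
    groups <- split(dat[[g]], dat$cell)
    groups <- purrr::map(groups, ~ .x[!is.na(.x)])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 3) {
      return(tibble(gene = g, n_groups = length(groups),
                    F = NA_real_, p = NA_real_))
    }
    res <- anova_tukey(groups)
    tibble(gene = g, n_groups = length(groups), F = res$F, p = res$p)
  }))
}

# Patient table augmented with high/low marker indicators from found
# survival cut-offs, ready for the prognostic workflow.
build_prognostic_table <- function(samples, patients, cuts) {
  rt <- samples |> filter(.data$compartment == "RT")
  dat <- patients |> left_join(rt |> select(-any_of(c("compartment",
                                                      "months_before_onset"))),
                               by = "patient_id")
  categorical <- intersect(c("initial_diagnosis", "depth_T", "node_N",
                             "metastasis_M", "stage", "ly", "v",
                             "inf_pattern", "lauren"), names(dat))
  for (ep in names(cuts)) {
    ct <- cuts[[ep]]
    if (is.null(ct)) next
    for (i in seq_len(nrow(ct))) {
      if (!isTRUE(ct$found[i])) next
      col <- paste0(ct$gene[i], "_high_", ep)
      dat[[col]] <- ifelse(dat[[ct$gene[i]]] >= ct$threshold[i], "HIGH", "LOW")
      categorical <- c(categorical, col)
    }
  }
  attr(dat, "categorical") <- unique(categorical)
  dat
}

#' Re-apply the published cut-offs (reference mode)
#'
#' Runs the pipeline with the published diagnostic and time-to-onset
#' thresholds injected as overrides, skipping cut-off discovery, on either
#' user data or the calibrated synthetic cohort. Optionally recomputes a
#' score distribution directly from printed per-score counts.
#'
#' @param config run config as in [run_full()] (defaults to the simulated
#'   study-sized cohort with the config's seed).
#' @param out_dir output directory.
#' @param score_counts optional named integer vector of per-score counts
#'   (names "0".."k"); if given, their distribution table is written as
#'   `reference_score_distribution.tsv` and returned.
#' @return the [run_full()] result, with `reference_score_distribution`
#'   appended when `score_counts` was supplied.
#' @export
reproduce_reference_mode <- function(config = list(simulate = TRUE, seed = 1L),
                                     out_dir, score_counts = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  if (length(cfg$genes) == 0) abort("empty gene subset",
                                    class = "methrisk_config_error")
  ref <- reference_cutoffs()
  cfg$cutoff_overrides$diagnostic <- cfg$cutoff_overrides$diagnostic %||% ref$diagnostic
  cfg$cutoff_overrides$term <- cfg$cutoff_overrides$term %||% ref$term
  run <- run_full(cfg, out_dir)
  if (!is.null(score_counts)) {
    expanded <- rep(as.integer(names(score_counts)), score_counts)
    dist <- score_distribution(expanded, k = max(as.integer(names(score_counts))))
    readr::write_tsv(dist, file.path(out_dir, "reference_score_distribution.tsv"),
                     progress = FALSE)
    run$reference_score_distribution <- dist
  }
  invisible(run)
}
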