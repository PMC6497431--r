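# Shared tabular data model: patients.tsv (one row per patient) and
# measurements.tsv (long; one row per patient x compartment x gene).
# TSV, header row, UTF-8, '.' decimal is the only dialect.

patient_label_sets <- function() {
  list(
    initial_diagnosis = c("MALIGNANT", "BENIGN"),
    sex = c("M", "F"),
    hp_status = c("POS", "NEG"),
    reconstruction = c("BI", "BII", "OTHER"),
    site = c("ANASTOMOTIC", "NON_ANASTOMOTIC"),
    depth_T = c("SM_OR_LESS", "MP_OR_DEEPER"),
    node_N = c("POS", "NEG"),
    metastasis_M = c("POS", "NEG"),
    stage = c("I", "II", "III", "IV"),
    ly = c("POS", "NEG"),
    v = c("POS", "NEG"),
    inf_pattern = c("a", "b", "c"),
    lauren = c("INTESTINAL", "DIFFUSE")
  )
}

patient_mandatory_cols <- function() {
  c("patient_id", "initial_diagnosis", "age", "sex", "term_to_rgc",
    "os_time", "os_event", "rfs_time", "rfs_event")
}

#' Read the patient clinical table
#'
#' Reads a tab-separated patient table (one row per patient) and validates
#' it against the clinical data model: initial diagnosis (MALIGNANT/BENIGN),
#' age, sex, term from the initial operation to remnant-cancer onset in
#' months, staging labels, and overall / relapse-free survival outcomes
#' clocked from the remnant-cancer surgery. Blank or absent categorical
#' values become `"UNKNOWN"`; a blank mandatory numeric field is an error.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble of validated patient records.
#' @seealso [validate_patients()], [read_measurements()]
#' @export
read_patients <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_patients(df)
}

#' Validate a patient table
#'
#' Type-converts and checks a patient data frame: mandatory columns
#' present, numeric fields parse, `term_to_rgc > 0`, survival times
#' non-negative with `rfs_time <= os_time`, and every categorical drawn
#' from its declared label set (blanks become `"UNKNOWN"`). Errors are
#' row-addressed.
#'
#' @param df data frame of patient records (character or typed columns).
#' @return a validated tibble with typed columns.
#' @export
validate_patients <- function(df) {
  labels <- patient_label_sets()
  missing_cols <- setdiff(patient_mandatory_cols(), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("patient table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methrisk_schema_error")
  }
  df <- as_tibble(df)

  num_col <- function(x, name) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value in column '%s' at row(s): %s",
                    name, paste(bad, collapse = ", ")),
            class = "methrisk_row_error")
    }
    out
  }
  bool_col <- function(x, name) {
    x <- toupper(trimws(as.character(x)))
    out <- dplyr::case_when(
      x %in% c("TRUE", "T", "1", "YES") ~ TRUE,
      x %in% c("FALSE", "F", "0", "NO") ~ FALSE,
      TRUE ~ NA
    )
    bad <- which(!is.na(x) & x != "" & is.na(out))
    if (length(bad) > 0) {
      abort(sprintf("non-boolean value in column '%s' at row(s): %s",
                    name, paste(bad, collapse = ", ")),
            class = "methrisk_row_error")
    }
    out
  }

  df$patient_id <- as.character(df$patient_id)
  df$age <- num_col(df$age, "age")
  df$term_to_rgc <- num_col(df$term_to_rgc, "term_to_rgc")
  df$os_time <- num_col(df$os_time, "os_time")
  df$rfs_time <- num_col(df$rfs_time, "rfs_time")
  df$os_event <- bool_col(df$os_event, "os_event")
  df$rfs_event <- bool_col(df$rfs_event, "rfs_event")

  for (col in names(labels)) {
    if (!col %in% names(df)) {
      df[[col]] <- "UNKNOWN"
      next
    }
    x <- trimws(as.character(df[[col]]))
    x[is.na(x) | x == ""] <- "UNKNOWN"
    bad <- which(!x %in% c(labels[[col]], "UNKNOWN"))
    if (length(bad) > 0) {
      abort(sprintf("column '%s' has value(s) outside {%s, UNKNOWN} at row(s): %s",
                    col, paste(labels[[col]], collapse = ", "),
                    paste(bad, collapse = ", ")),
            class = "methrisk_row_error")
    }
    df[[col]] <- x
  }

  check_rows <- function(bad, msg) {
    if (length(bad) > 0) {
      abort(sprintf("%s at row(s): %s", msg, paste(bad, collapse = ", ")),
            class = "methrisk_row_error")
    }
  }
  check_rows(which(duplicated(df$patient_id)), "duplicate patient_id")
  check_rows(which(is.na(df$age) | df$age <= 0), "age must be a positive number")
  check_rows(which(is.na(df$term_to_rgc) | df$term_to_rgc <= 0),
             "term_to_rgc must be > 0")
  check_rows(which(!is.na(df$os_time) & df$os_time < 0), "os_time must be >= 0")
  check_rows(which(!is.na(df$rfs_time) & df$rfs_time < 0), "rfs_time must be >= 0")
  check_rows(which(!is.na(df$os_time) & !is.na(df$rfs_time) &
                     df$rfs_time > df$os_time + 1e-9),
             "rfs_time must not exceed os_time")
  df
}

#' Read the methylation measurement table
#'
#' Reads a long-format TSV (`patient_id`, `compartment`, `gene`,
#' `taqmeth_v`, `months_before_onset`) and pivots it to one row per tissue
#' sample with one column per panel gene. A gene never reported for a
#' sample stays `NA` (missing), never 0: a TaqMeth V of 0 is a legitimate
#' Q-MSP result (undetected methylation), absence of the assay is not.
#'
#' @param path path to a TSV file with a header row.
#' @return a tibble with columns `patient_id`, `compartment`,
#'   `months_before_onset`, and one numeric column per gene
#'   (`CDO1`, `HOPX`, `Reprimo`, `ECAD`).
#' @export
read_measurements <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  validate_measurements(df)
}

#' Validate and pivot a long measurement table
#'
#' @param df long data frame with columns `patient_id`, `compartment`,
#'   `gene`, `taqmeth_v` and optionally `months_before_onset`.
#' @return wide sample tibble (see [read_measurements()]).
#' @export
validate_measurements <- function(df) {
  need <- c("patient_id", "compartment", "gene", "taqmeth_v")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("measurement table is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methrisk_schema_error")
  }
  df <- as_tibble(df)
  if (!"months_before_onset" %in% names(df)) df$months_before_onset <- NA_character_
  df$patient_id <- as.character(df$patient_id)
  df$compartment <- trimws(as.character(df$compartment))
  df$gene <- trimws(as.character(df$gene))
  df$taqmeth_v <- suppressWarnings(as.numeric(df$taqmeth_v))
  df$months_before_onset <- suppressWarnings(as.numeric(as.character(df$months_before_onset)))

  bad_gene <- unique(df$gene[!df$gene %in% PANEL_GENES])
  if (length(bad_gene) > 0) {
    abort(paste0("unknown gene symbol(s): ", paste(bad_gene, collapse = ", "),
                 "; expected one of ", paste(PANEL_GENES, collapse = ", ")),
          class = "methrisk_schema_error")
  }
  bad_comp <- unique(df$compartment[!df$compartment %in% COMPARTMENTS])
  if (length(bad_comp) > 0) {
    abort(paste0("unknown compartment(s): ", paste(bad_comp, collapse = ", ")),
          class = "methrisk_schema_error")
  }
  if (any(!is.na(df$taqmeth_v) & df$taqmeth_v < 0)) {
    abort("taqmeth_v must be >= 0", class = "methrisk_row_error")
  }
  biopsy_missing <- df$compartment == "BIOPSY" & is.na(df$months_before_onset)
  if (any(biopsy_missing)) {
    abort(sprintf("BIOPSY rows must carry months_before_onset (row(s): %s)",
                  paste(which(biopsy_missing), collapse = ", ")),
          class = "methrisk_row_error")
  }
  key <- paste(df$patient_id, df$compartment, df$gene,
               ifelse(is.na(df$months_before_onset), "", df$months_before_onset))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate measurement for (patient, compartment, gene, months): ", dup),
          class = "methrisk_conflict_error")
  }

  wide <- df |>
    pivot_wider(id_cols = c("patient_id", "compartment", "months_before_onset"),
                names_from = "gene", values_from = "taqmeth_v")
  for (g in PANEL_GENES) if (!g %in% names(wide)) wide[[g]] <- NA_real_
  wide |>
    select(all_of(c("patient_id", "compartment", "months_before_onset", PANEL_GENES))) |>
    arrange(.data$patient_id, .data$compartment, .data$months_before_onset)
}

#' Write a wide sample table back to the long measurement format
#'
#' Inverse of [read_measurements()]: missing (`NA`) gene values are dropped
#' from the long output rather than written as 0.
#'
#' @param samples wide sample tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(samples, path) {
  long <- samples |>
    pivot_longer(cols = all_of(intersect(PANEL_GENES, names(samples))),
                 names_to = "gene", values_to = "taqmeth_v") |>
    filter(!is.na(.data$taqmeth_v)) |>
    select(all_of(c("patient_id", "compartment", "gene", "taqmeth_v",
                    "months_before_onset")))
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Write patient records to TSV
#'
#' @param patients patient tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  readr::write_tsv(patients, path, progress = FALSE)
  invisible(path)
}

#' Write a set of report tables
#'
#' Writes each data frame in a named list to `<out_dir>/<name>.tsv` with a
#' deterministic column order (as given). Floats survive a write/read
#' round trip to at least 12 significant digits; integers and strings
#' exactly.
#'
#' @param results named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the paths written, invisibly.
#' @export
write_report_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(results[[nm]]), p, progress = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read and validate a run configuration file
#'
#' The run configuration is a single YAML (or JSON, a YAML subset) file.
#' Recognised keys: `genes` (subset of the panel), `alpha` (significance
#' level, in (0,1)), `min_group_frac` (minimum group fraction for cut-point
#' scans, in (0, 0.5)), `seed` (integer), `cutoff_overrides` (named list
#' `purpose -> gene -> threshold`), `paths` (input/output file paths) and
#' `simulate` (generator settings handed to [generator_config()]).
#'
#' @param path path to the YAML config file.
#' @return validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Default run configuration
#' @return config list with package defaults.
#' @export
default_run_config <- function() {
  list(
    genes = PANEL_GENES,
    alpha = 0.05,
    min_group_frac = 0.1,
    seed = 1L,
    cutoff_overrides = list(),
    paths = list(),
    simulate = NULL
  )
}

#' Validate a run configuration list
#' @param cfg config list.
#' @return validated config list with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  out <- utils::modifyList(default_run_config(), cfg)
  if (!all(out$genes %in% PANEL_GENES)) {
    abort(paste0("config genes must be a subset of: ",
                 paste(PANEL_GENES, collapse = ", ")))
  }
  if (length(out$genes) == 0) abort("config genes must be non-empty")
  if (!is.numeric(out$alpha) || out$alpha <= 0 || out$alpha >= 1) {
    abort("config alpha must be in (0, 1)")
  }
  if (!is.numeric(out$min_group_frac) ||
      out$min_group_frac <= 0 || out$min_group_frac >= 0.5) {
    abort("config min_group_frac must be in (0, 0.5)")
  }
  if (is.null(out$seed) || is.na(suppressWarnings(as.integer(out$seed)))) {
    abort("config seed must be an integer")
  }
  out$seed <- as.integer(out$seed)
  for (purpose in names(out$cutoff_overrides)) {
    ov <- out$cutoff_overrides[[purpose]]
    if (!all(names(ov) %in% PANEL_GENES)) {
      abort(paste0("cutoff_overrides for '", purpose,
                   "' name genes outside the panel"))
    }
  }
  out
}
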