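# TaqMeth V quantification from Q-MSP replicate quantities.
# TaqMeth V = 100 * (methylated-target quantity) / (beta-actin quantity).

#' Aggregate Q-MSP replicate quantities
#'
#' Replicates (typically triplicates) are aggregated by arithmetic mean
#' before the target/reference ratio is formed; the mean is linear in the
#' quantities, so aggregating before or after a common rescaling is
#' equivalent.
#'
#' @param quantities numeric vector of non-negative per-replicate
#'   amplification quantities.
#' @return the mean quantity (scalar).
#' @export
aggregate_replicates <- function(quantities) {
  if (length(quantities) == 0) {
    abort("at least one replicate quantity is required",
          class = "methrisk_domain_error")
  }
  if (any(is.na(quantities)) || any(quantities < 0)) {
    abort("replicate quantities must be non-negative and non-missing",
          class = "methrisk_domain_error")
  }
  mean(quantities)
}

#' Compute the TaqMeth methylation value
#'
#' `100 * target_q / actin_q`. A non-positive beta-actin quantity means the
#' reference reaction failed; the sample must be excluded, not scored 0 —
#' conflating reference failure with absent methylation would bias
#' downstream cut-offs low. Vectorised over both arguments.
#'
#' @param target_q methylated-target amplification quantity (>= 0).
#' @param actin_q beta-actin reference quantity (> 0).
#' @return TaqMeth V, a non-negative value on the gene's native scale.
#' @export
taqmeth_value <- function(target_q, actin_q) {
  if (any(is.na(actin_q)) || any(actin_q <= 0)) {
    abort("beta-actin quantity must be > 0 (reference failed: exclude the sample)",
          class = "methrisk_invalid_sample_error")
  }
  if (any(is.na(target_q)) || any(target_q < 0)) {
    abort("target quantity must be >= 0", class = "methrisk_domain_error")
  }
  100 * target_q / actin_q
}

#' Compile raw replicate quantities into a measurement table
#'
#' Takes a raw-quantity table (`patient_id`, `compartment`, `gene`,
#' `replicate`, `target_q`, `actin_q`, optionally `months_before_onset`),
#' aggregates replicates per well by mean, and computes TaqMeth V. Wells
#' whose aggregated beta-actin quantity is non-positive are excluded with a
#' warning naming how many were dropped.
#'
#' @param raw data frame of per-replicate quantities.
#' @return long measurement tibble (`patient_id`, `compartment`, `gene`,
#'   `taqmeth_v`, `months_before_onset`) ready for [validate_measurements()].
#' @export
compile_qmsp <- function(raw) {
  need <- c("patient_id", "compartment", "gene", "target_q", "actin_q")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("raw Q-MSP table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methrisk_schema_error")
  }
  raw <- as_tibble(raw)
  if (!"months_before_onset" %in% names(raw)) raw$months_before_onset <- NA_real_
  agg <- raw |>
    group_by(.data$patient_id, .data$compartment, .data$gene,
             .data$months_before_onset) |>
    summarise(target_q = aggregate_replicates(.data$target_q),
              actin_q = aggregate_replicates(.data$actin_q),
              .groups = "drop")
  failed <- agg$actin_q <= 0
  if (any(failed)) {
    warn(sprintf("excluded %d well(s) with failed beta-actin reference", sum(failed)))
    agg <- agg[!failed, , drop = FALSE]
  }
  agg |>
    mutate(taqmeth_v = taqmeth_value(.data$target_q, .data$actin_q)) |>
    select(all_of(c("patient_id", "compartment", "gene", "taqmeth_v",
                    "months_before_onset")))
}
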