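# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: two initial-diagnosis groups with widely
# separated onset terms, zero-inflated right-skewed per-gene TaqMeth V
# distributions moment-matched to published compartment summaries, a
# positively correlated CDO1/HOPX/Reprimo trio with E-cadherin
# independent, biopsy methylation weakly negatively coupled to the
# remaining time to onset, and stage-linked exponential survival.

#' Log-normal parameters from target arithmetic moments
#'
#' Moment matching: a log-normal with `meanlog = mu`, `sdlog = sigma` has
#' arithmetic mean `m` and SD `s` when `sigma^2 = log(1 + (s/m)^2)` and
#' `mu = log(m) - sigma^2 / 2`.
#'
#' @param m target arithmetic mean (> 0).
#' @param s target arithmetic SD (>= 0).
#' @return named numeric vector `c(meanlog, sdlog)`.
#' @export
lognormal_from_moments <- function(m, s) {
  if (!is.numeric(m) || is.na(m) || m <= 0) {
    abort("target mean must be > 0", class = "methrisk_domain_error")
  }
  if (!is.numeric(s) || is.na(s) || s < 0) {
    abort("target SD must be >= 0", class = "methrisk_domain_error")
  }
  sigma2 <- log1p((s / m)^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# Log-normal parameters of the non-zero part of a zero-inflated
# log-normal whose OVERALL mean and SD are (m, s) at zero-mass pi0.
# Overall mean = (1-pi0) * m1 and overall E[X^2] = (1-pi0) * E1[X^2].
# Feasible only for pi0 < s^2 / (m^2 + s^2).
zi_lognormal_params <- function(m, s, pi0) {
  stopifnot(pi0 >= 0, pi0 < 1)
  if (pi0 == 0) return(lognormal_from_moments(m, s))
  m1 <- m / (1 - pi0)
  ex2 <- (m^2 + s^2) / (1 - pi0)
  s1sq <- ex2 - m1^2
  if (s1sq <= 0) {
    abort(sprintf("zero-inflation pi0 = %.3f infeasible for mean %.3g, SD %.3g (ceiling %.3f)",
                  pi0, m, s, s^2 / (m^2 + s^2)),
          class = "methrisk_domain_error")
  }
  lognormal_from_moments(m1, sqrt(s1sq))
}

#' Calibrate the zero-inflation mass to a printed exceedance proportion
#'
#' Finds the zero-mass `pi0` such that a zero-inflated log-normal with
#' overall mean `m` and SD `s` has `P(V >= cutoff)` as close as possible to
#' `target_prop`. `pi0` is bounded above by `s^2/(m^2+s^2)` (beyond that
#' the non-zero part's variance would be negative); when the target
#' proportion is unattainable within that range the closest feasible value
#' is returned.
#'
#' @param m,s overall target mean and SD.
#' @param cutoff threshold whose exceedance proportion is matched.
#' @param target_prop target `P(V >= cutoff)` in `[0, 1]`.
#' @return scalar `pi0` in `[0, 1)`.
#' @export
calibrate_zero_inflation <- function(m, s, cutoff, target_prop) {
  stopifnot(m > 0, s > 0, cutoff > 0, target_prop >= 0, target_prop <= 1)
  ceiling_pi0 <- s^2 / (m^2 + s^2)
  grid <- seq(0, max(0, ceiling_pi0 - 1e-4), length.out = 2001)
  tail_prob <- vapply(grid, function(p0) {
    par <- zi_lognormal_params(m, s, p0)
    (1 - p0) * plnorm(cutoff, par["meanlog"], par["sdlog"], lower.tail = FALSE)
  }, numeric(1))
  grid[which.min(abs(tail_prob - target_prop))]
}

#' Default per-compartment per-gene methylation distribution parameters
#'
#' Overall means/SDs for each compartment cell (RT, RN, IN of
#' initially-malignant patients, IN of initially-benign patients) with the
#' RT/RN zero-inflation masses calibrated so the modelled fraction
#' exceeding the diagnostic cut-offs (6.49 / 4.14 / 2.59 / 1.09) matches
#' the published exceedance proportions; IN cells have no published
#' proportions and use `pi0 = 0`.
#'
#' @return tibble with columns `cell`, `gene`, `m`, `s`, `pi0`.
#' @export
default_methylation_params <- function() {
  ref <- tribble(
    ~cell,    ~gene,     ~m,    ~s,    ~cutoff, ~prop_above,
    "RT",     "CDO1",    16.90, 12.08, 6.49,    0.828,
    "RT",     "HOPX",    10.07, 10.56, 4.14,    0.655,
    "RT",     "Reprimo", 10.63, 21.43, 2.59,    0.534,
    "RT",     "ECAD",    0.26,  0.77,  1.09,    0.103,
    "RN",     "CDO1",    3.71,  4.74,  6.49,    0.138,
    "RN",     "HOPX",    2.13,  2.92,  4.14,    0.155,
    "RN",     "Reprimo", 0.62,  1.52,  2.59,    0.052,
    "RN",     "ECAD",    0.081, 0.19,  1.09,    0.000,
    "IN_IM",  "CDO1",    13.1,  13.3,  NA,      NA,
    "IN_IM",  "HOPX",    3.6,   4.7,   NA,      NA,
    "IN_IM",  "Reprimo", 0.8,   2.2,   NA,      NA,
    "IN_IM",  "ECAD",    0.1,   0.1,   NA,      NA,
    "IN_IB",  "CDO1",    4.2,   5.6,   NA,      NA,
    "IN_IB",  "HOPX",    1.2,   1.7,   NA,      NA,
    "IN_IB",  "Reprimo", 0.5,   0.9,   NA,      NA,
    "IN_IB",  "ECAD",    0.3,   0.2,   NA,      NA
  )
  ref$pi0 <- mapply(function(m, s, cutoff, p) {
    if (is.na(cutoff)) 0 else calibrate_zero_inflation(m, s, cutoff, p)
  }, ref$m, ref$s, ref$cutoff, ref$prop_above)
  ref |> select(all_of(c("cell", "gene", "m", "s", "pi0")))
}

#' Build a synthetic-cohort generator configuration
#'
#' All distributional knobs in one validated list. Defaults reproduce the
#' published study conditions: 35 initially-malignant / 23 initially-benign
#' patients; onset terms from truncated normals 191.5 +/- 127.5 and
#' 485.7 +/- 86.7 months; per-compartment methylation from
#' [default_methylation_params()]; Gaussian-copula correlation 0.6 among
#' CDO1/HOPX/Reprimo with E-cadherin independent; 17 / 12 initial-surgery
#' mucosa samples; 43 biopsies from 12 initially-malignant patients with
#' mean lead time 83.6 +/- 78.5 months; stage-linked exponential survival
#' censored administratively at 60 months.
#'
#' @param seed integer random seed (mandatory).
#' @param n_malignant,n_benign group sizes.
#' @param term_malignant,term_benign `c(mean, sd)` of onset terms, months.
#' @param term_lower truncation lower bound of the term distribution.
#' @param methylation tibble as from [default_methylation_params()].
#' @param rho copula correlation among the CDO1/HOPX/Reprimo trio.
#' @param rn_im_mean_scale multiplicative shift of RN means for the
#'   initially-malignant group (1 = pooled RN parameters for both groups).
#' @param n_in_malignant,n_in_benign initial-surgery mucosa subset sizes.
#' @param n_biopsy_patients,n_biopsies biopsy series shape.
#' @param biopsy_lead_mean,biopsy_lead_sd months-before-onset distribution.
#' @param biopsy_coupling named per-gene latent coupling strengths in
#'   `[0, 1)` tying biopsy methylation negatively to the remaining time.
#' @param age_mean,age_sd,p_male demographic draws.
#' @param p_stage_ge_iii probability of composite stage III/IV.
#' @param base_rate_os baseline OS hazard per month (stage <= II).
#' @param rfs_rate_mult relapse hazard multiplier relative to OS.
#' @param hr_stage hazard ratio for stage III/IV.
#' @param censor_months administrative censoring horizon (5-year follow-up).
#' @return validated config list of class `"rgc_generator_config"`.
#' @export
generator_config <- function(seed,
                             n_malignant = 35, n_benign = 23,
                             term_malignant = c(mean = 191.5, sd = 127.5),
                             term_benign = c(mean = 485.7, sd = 86.7),
                             term_lower = 1,
                             methylation = default_methylation_params(),
                             rho = 0.6,
                             rn_im_mean_scale = 1,
                             n_in_malignant = 17, n_in_benign = 12,
                             n_biopsy_patients = 12, n_biopsies = 43,
                             biopsy_lead_mean = 83.6, biopsy_lead_sd = 78.5,
                             biopsy_coupling = c(CDO1 = 0.21, HOPX = 0.31,
                                                 Reprimo = 0.54, ECAD = 0.065),
                             age_mean = 70, age_sd = 9,
                             p_male = 51 / 58,
                             p_stage_ge_iii = 12 / 58,
                             base_rate_os = 0.012,
                             rfs_rate_mult = 1.3,
                             hr_stage = 3,
                             censor_months = 60) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    abort("generator seed is mandatory", class = "methrisk_config_error")
  }
  cfg <- list(seed = as.integer(seed),
              n_malignant = n_malignant, n_benign = n_benign,
              term_malignant = term_malignant, term_benign = term_benign,
              term_lower = term_lower, methylation = as_tibble(methylation),
              rho = rho, rn_im_mean_scale = rn_im_mean_scale,
              n_in_malignant = n_in_malignant, n_in_benign = n_in_benign,
              n_biopsy_patients = n_biopsy_patients, n_biopsies = n_biopsies,
              biopsy_lead_mean = biopsy_lead_mean, biopsy_lead_sd = biopsy_lead_sd,
              biopsy_coupling = biopsy_coupling,
              age_mean = age_mean, age_sd = age_sd, p_male = p_male,
              p_stage_ge_iii = p_stage_ge_iii,
              base_rate_os = base_rate_os, rfs_rate_mult = rfs_rate_mult,
              hr_stage = hr_stage, censor_months = censor_months)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_malignant <= 0 || cfg$n_benign <= 0) {
    abort("group sizes must be positive", class = "methrisk_config_error")
  }
  if (any(cfg$methylation$s <= 0)) {
    abort("all methylation SDs must be > 0", class = "methrisk_config_error")
  }
  if (any(cfg$methylation$pi0 < 0 | cfg$methylation$pi0 >= 1)) {
    abort("pi0 must be in [0, 1)", class = "methrisk_config_error")
  }
  if (abs(cfg$rho) >= 1) abort("copula rho must be in (-1, 1)",
                               class = "methrisk_config_error")
  if (any(cfg$biopsy_coupling < 0 | cfg$biopsy_coupling >= 1)) {
    abort("biopsy coupling must be in [0, 1)", class = "methrisk_config_error")
  }
  if (!setequal(names(cfg$biopsy_coupling), PANEL_GENES)) {
    abort("biopsy_coupling must name every panel gene",
          class = "methrisk_config_error")
  }
  structure(cfg, class = "rgc_generator_config")
}

# Truncated-normal draws via inverse CDF (exact, vectorised).
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Copula correlation matrix: rho among the trio, E-cadherin independent.
panel_copula_matrix <- function(rho) {
  R <- diag(4)
  dimnames(R) <- list(PANEL_GENES, PANEL_GENES)
  trio <- c("CDO1", "HOPX", "Reprimo")
  R[trio, trio] <- rho
  diag(R) <- 1
  R
}

# n x 4 latent standard-normal draws with the panel copula correlation.
panel_latent <- function(n, rho) {
  U <- chol(panel_copula_matrix(rho))
  Z <- matrix(rnorm(n * 4), nrow = n) %*% U
  colnames(Z) <- PANEL_GENES
  Z
}

# Map latent standard normals to zero-inflated log-normal values for one
# compartment cell. params: tibble rows for the cell keyed by gene.
latent_to_values <- function(Z, params) {
  out <- matrix(NA_real_, nrow = nrow(Z), ncol = length(PANEL_GENES),
                dimnames = list(NULL, PANEL_GENES))
  for (g in PANEL_GENES) {
    row <- params[params$gene == g, ]
    par <- zi_lognormal_params(row$m, row$s, row$pi0)
    u <- pnorm(Z[, g])
    v <- numeric(nrow(Z))
    nz <- u >= row$pi0
    v[nz] <- qlnorm((u[nz] - row$pi0) / (1 - row$pi0), par["meanlog"], par["sdlog"])
    out[, g] <- v
  }
  out
}

cell_params <- function(cfg, cell) {
  p <- cfg$methylation[cfg$methylation$cell == cell, ]
  if (nrow(p) != 4) abort(paste0("methylation parameters missing for cell ", cell),
                          class = "methrisk_config_error")
  p
}

draw_cell_samples <- function(patients_idx, cell, compartment, cfg,
                              mean_scale = 1) {
  n <- length(patients_idx)
  params <- cell_params(cfg, cell)
  if (mean_scale != 1) params$m <- params$m * mean_scale
  vals <- latent_to_values(panel_latent(n, cfg$rho), params)
  as_tibble(vals) |>
    mutate(patient_id = patients_idx, compartment = compartment,
           months_before_onset = NA_real_, .before = 1)
}

#' Draw methylation samples for one compartment cell
#'
#' Direct draws from the configured zero-inflated log-normal copula for a
#' cell (`"RT"`, `"RN"`, `"IN_IM"`, `"IN_IB"`), mainly for calibration
#' checks. Uses the current RNG state.
#'
#' @param n number of samples.
#' @param cell compartment cell name.
#' @param config a [generator_config()].
#' @return n x 4 tibble of TaqMeth V values (one column per gene).
#' @export
sample_methylation <- function(n, cell, config) {
  cfg <- validate_generator_config(config)
  as_tibble(latent_to_values(panel_latent(n, cfg$rho), cell_params(cfg, cell)))
}

#' Generate a synthetic remnant-gastric-cancer cohort
#'
#' Deterministic given the config seed. Draws patients (diagnosis groups,
#' truncated-normal onset terms, demographics and staging labels with the
#' published marginal frequencies), per-patient remnant tumor (RT) and
#' remnant mucosa (RN) methylation samples, initial-surgery mucosa (IN)
#' samples for the configured subsets (malignant-group IN uses the IN-IM
#' parameters, benign-group IN the IN-IB parameters), and stage-linked
#' survival outcomes.
#'
#' @param config a [generator_config()].
#' @return object of class `"rgc_cohort"`: a list with tibbles `patients`
#'   and `samples` plus the `config`.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_malignant + cfg$n_benign
  diagnosis <- rep(c("MALIGNANT", "BENIGN"), c(cfg$n_malignant, cfg$n_benign))

  term <- numeric(n)
  im <- diagnosis == "MALIGNANT"
  term[im] <- rtrunc_norm(sum(im), cfg$term_malignant[["mean"]],
                          cfg$term_malignant[["sd"]], lower = cfg$term_lower)
  term[!im] <- rtrunc_norm(sum(!im), cfg$term_benign[["mean"]],
                           cfg$term_benign[["sd"]], lower = cfg$term_lower)

  stage_hi <- runif(n) < cfg$p_stage_ge_iii
  metastasis <- ifelse(runif(n) < 2 / 58 & stage_hi, "POS", "NEG")
  stage <- ifelse(stage_hi,
                  ifelse(metastasis == "POS", "IV", "III"),
                  ifelse(runif(n) < 0.5, "I", "II"))
  hp <- rep("UNKNOWN", n)
  hp_known <- sample.int(n, min(11, n))
  hp[hp_known] <- ifelse(runif(length(hp_known)) < 5 / 11, "POS", "NEG")

  patients <- tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    initial_diagnosis = diagnosis,
    age = pmax(30, round(rnorm(n, cfg$age_mean, cfg$age_sd))),
    sex = ifelse(runif(n) < cfg$p_male, "M", "F"),
    term_to_rgc = term,
    hp_status = hp,
    reconstruction = sample(c("BI", "BII", "OTHER"), n, replace = TRUE,
                            prob = c(38, 16, 4) / 58),
    site = ifelse(runif(n) < 30 / 58, "ANASTOMOTIC", "NON_ANASTOMOTIC"),
    depth_T = ifelse(runif(n) < 0.5, "SM_OR_LESS", "MP_OR_DEEPER"),
    node_N = ifelse(runif(n) < 45 / 58, "POS", "NEG"),
    metastasis_M = metastasis,
    stage = stage,
    ly = ifelse(runif(n) < 23 / 58, "POS", "NEG"),
    v = ifelse(runif(n) < 21 / 58, "POS", "NEG"),
    inf_pattern = sample(c("a", "b", "c"), n, replace = TRUE,
                         prob = c(8, 17, 33) / 58),
    lauren = ifelse(runif(n) < 0.5, "INTESTINAL", "DIFFUSE")
  )
  patients <- generate_survival(patients, cfg)

  rt <- draw_cell_samples(patients$patient_id, "RT", "RT", cfg)
  rn_im <- draw_cell_samples(patients$patient_id[im], "RN", "RN", cfg,
                             mean_scale = cfg$rn_im_mean_scale)
  rn_ib <- draw_cell_samples(patients$patient_id[!im], "RN", "RN", cfg)
  in_im_ids <- patients$patient_id[im][seq_len(min(cfg$n_in_malignant, sum(im)))]
  in_ib_ids <- patients$patient_id[!im][seq_len(min(cfg$n_in_benign, sum(!im)))]
  in_im <- draw_cell_samples(in_im_ids, "IN_IM", "IN", cfg)
  in_ib <- draw_cell_samples(in_ib_ids, "IN_IB", "IN", cfg)

  samples <- bind_rows(rt, rn_im, rn_ib, in_im, in_ib) |>
    select(all_of(c("patient_id", "compartment", "months_before_onset",
                    PANEL_GENES))) |>
    arrange(.data$patient_id, .data$compartment)

  structure(list(patients = patients, samples = samples, config = cfg),
            class = "rgc_cohort")
}

#' @export
print.rgc_cohort <- function(x, ...) {
  cat("Synthetic RGC cohort:", nrow(x$patients), "patients,",
      nrow(x$samples), "tissue samples",
      sprintf("(seed %d)\n", x$config$seed))
  cat("  diagnosis:", sum(x$patients$initial_diagnosis == "MALIGNANT"),
      "malignant /", sum(x$patients$initial_diagnosis == "BENIGN"), "benign\n")
  cat("  compartments:",
      paste(names(table(x$samples$compartment)),
            table(x$samples$compartment), collapse = ", "), "\n")
  invisible(x)
}

#' Generate an endoscopic biopsy series
#'
#' Selects initially-malignant patients and gives each one or more BIOPSY
#' samples. `months_before_onset` is drawn from a truncated normal (lower
#' bound 1, upper bound the patient's own onset term) targeting the
#' configured mean lead time; gene values use the remnant-mucosa (RN)
#' distribution with a negative latent coupling to the lead time, so that
#' shorter remaining time goes with higher methylation and the fitted
#' value-on-months r-squared is weak, as observed.
#'
#' @param patients patient tibble from [generate_cohort()].
#' @param config the same [generator_config()].
#' @return tibble of BIOPSY samples in the wide sample layout.
#' @export
generate_biopsy_series <- function(patients, config) {
  cfg <- validate_generator_config(config)
  im <- patients[patients$initial_diagnosis == "MALIGNANT", ]
  n_pat <- min(cfg$n_biopsy_patients, nrow(im))
  if (n_pat == 0) abort("no initially-malignant patients to biopsy",
                        class = "methrisk_config_error")
  chosen <- im[sample.int(nrow(im), n_pat), ]
  # each chosen patient gets >= 1 biopsy; the remainder spread at random
  extra <- cfg$n_biopsies - n_pat
  if (extra < 0) abort("n_biopsies must be >= n_biopsy_patients",
                       class = "methrisk_config_error")
  alloc <- rep(1L, n_pat) + as.vector(stats::rmultinom(1, extra, rep(1, n_pat)))
  idx <- rep(seq_len(n_pat), alloc)
  n <- length(idx)

  upper <- chosen$term_to_rgc[idx]
  plo <- pnorm(1, cfg$biopsy_lead_mean, cfg$biopsy_lead_sd)
  phi <- pnorm(upper, cfg$biopsy_lead_mean, cfg$biopsy_lead_sd)
  u_time <- plo + runif(n) * (phi - plo)
  months <- qnorm(u_time, cfg$biopsy_lead_mean, cfg$biopsy_lead_sd)
  z_time <- qnorm(u_time)  # standard-normal score of the lead time

  eps <- panel_latent(n, cfg$rho)
  params <- cell_params(cfg, "RN")
  Z <- matrix(NA_real_, n, 4, dimnames = list(NULL, PANEL_GENES))
  for (g in PANEL_GENES) {
    cg <- cfg$biopsy_coupling[[g]]
    Z[, g] <- -sqrt(cg) * z_time + sqrt(1 - cg) * eps[, g]
  }
  vals <- latent_to_values(Z, params)

  as_tibble(vals) |>
    mutate(patient_id = chosen$patient_id[idx], compartment = "BIOPSY",
           months_before_onset = months, .before = 1) |>
    select(all_of(c("patient_id", "compartment", "months_before_onset",
                    PANEL_GENES)))
}

#' Fill stage-linked survival outcomes
#'
#' Exponential event times with a configurable hazard ratio for composite
#' stage III/IV, administratively censored at the follow-up horizon
#' (default 60 months, i.e. five-year OS/RFS). Relapse shares the stage
#' effect, runs at `rfs_rate_mult` times the OS hazard, and is capped at
#' the observed OS time so `rfs_time <= os_time` always. A zero hazard
#' yields infinite latent times, hence universal censoring.
#'
#' @param patients patient tibble (needs a `stage` column).
#' @param config a [generator_config()].
#' @return `patients` with `os_time`, `os_event`, `rfs_time`, `rfs_event`.
#' @export
generate_survival <- function(patients, config) {
  cfg <- validate_generator_config(config)
  n <- nrow(patients)
  hr <- ifelse(patients$stage %in% c("III", "IV"), cfg$hr_stage, 1)
  draw_exp <- function(rates) {
    t <- rep(Inf, length(rates))
    pos <- rates > 0
    t[pos] <- rexp(sum(pos), rates[pos])
    t
  }
  t_os <- draw_exp(cfg$base_rate_os * hr)
  t_rfs <- draw_exp(cfg$base_rate_os * cfg$rfs_rate_mult * hr)
  cens <- cfg$censor_months
  patients$os_time <- pmin(t_os, cens)
  patients$os_event <- t_os <= cens
  patients$rfs_time <- pmin(t_rfs, patients$os_time)
  patients$rfs_event <- t_rfs <= patients$os_time & t_rfs <= cens
  patients
}
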