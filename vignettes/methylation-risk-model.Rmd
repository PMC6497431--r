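---
title: "The four-gene methylation risk model for remnant gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-gene methylation risk model for remnant gastric cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Remnant gastric cancer (RGC) arises in the residual stomach years to
decades after a partial gastrectomy. Surveillance endoscopy over such
horizons has poor compliance, so a tissue biomarker that stratifies
*when* a patient is likely to develop RGC is clinically valuable.
Promoter hypermethylation of **CDO1**, **HOPX**, **Reprimo** and
**E-cadherin** accumulates in histologically normal mucosa ("epigenetic
field cancerization") and is the signal this package quantifies and
models.

Methylation is measured by quantitative methylation-specific PCR
(Q-MSP) on bisulfite-converted DNA. The unit throughout is the
**TaqMeth V**: the methylated-target amplification quantity divided by
the beta-actin reference quantity, times 100. Replicate wells are
aggregated by arithmetic mean *before* the ratio; a failed beta-actin
reaction excludes the sample rather than scoring it 0, because a true
0 is a legitimate result (undetected methylation) while a reference
failure is not. Values stay on their native per-gene scales — the
E-cadherin assay has intrinsically lower PCR affinity, so cross-gene
comparability is not assumed anywhere; every threshold is per-gene.

## The model

The analysis pipeline has four statistical stages.

**Cut-off discovery.** Three procedures, all scanning the observed
unique marker values as candidate thresholds with `value >= theta` as
the positive call (the same convention the scoring rule uses):

* *Diagnostic* (tumor vs remnant mucosa): maximise Youden's
  J = sensitivity + specificity − 1; ties break toward the larger
  threshold, favouring specificity. AUC is the Mann–Whitney all-pairs
  concordance with ties counted one half.
* *Survival* (OS/RFS): minimum-p log-rank scan. Candidates leaving
  either group below `ceil(min_group_frac * n)` members are skipped
  (default fraction 0.1). If no eligible candidate reaches `p < 0.05`,
  the result is "no optimal cut-off obtained" (`found = FALSE`) — a
  finding, not an error. The reported relative risk is the univariate
  Cox hazard ratio of the high-methylation indicator.
* *Time to onset* (biopsies): minimum-p pooled-variance Student t-test
  scan of the months-before-onset between the `>= theta` and `< theta`
  groups, with the same eligibility rule. Sensitivity/specificity are
  reported descriptively against the label "term at or below the
  cohort median".

Minimum-p selection is anti-conservative: scanning many candidate
splits and keeping the smallest p inflates type-I error. The package
keeps the uncorrected p primary (matching how such thresholds are
reported in the clinical literature), emits a warning in every
pipeline run, and offers a permutation-adjusted minimum-p
(`n_perm > 0`) for honest inference.

**Risk score.** Each gene contributes 1 point when its TaqMeth V is at
or above its cut-off, 0 below; the score is the unweighted sum, 0–4
over the full panel. A missing measurement propagates as missing —
incomplete panels are excluded from score distributions rather than
zero-filled, because zero-filling deflates scores asymmetrically. The
headline dichotomy is score 0–1 vs 2–4. The combination table
enumerates every subset (pairs of the CDO1/HOPX/Reprimo trio, the
trio, all four genes) crossed with every split of its score: binary
splits are tested with the pooled t, all-level rows with one-way
ANOVA (the natural k-group test given a single reported p per row).

**Survival analysis.** Kaplan–Meier curves, two-group log-rank tests,
and Cox proportional-hazards models with Efron tie handling (the
modern default; the original analyses were run in JMP, which does not
document its choice). Both endpoints are clocked from the RGC surgery
and administratively censored at 60 months (five-year OS/RFS). The
prognostic workflow screens factors univariately at p < 0.05
(categorical by log-rank, continuous by univariate Cox) and fits a
multivariate Cox on the survivors, excluding the individual T/N/M
components whenever composite stage passes the screen — they are
constituents of stage, not independent factors.

**Propensity model.** An unregularised logistic regression of the
initial diagnosis (malignant vs benign) on remnant-mucosa methylation,
optionally plus age, sex and the term to onset. Discrimination is the
*in-sample* (apparent) AUC — that is what the published 0.7 → 0.94
figures are, fitted and evaluated on the same 58 patients — and the
package says so in its logs; a k-fold cross-validated AUC is reported
alongside as honesty output. Complete separation is flagged, not
silently penalised. The term covariate enters in raw months (no
transform is documented for it, so none is applied).

## The synthetic cohort generator

No patient-level data are deposited, so the generator exists to
exercise every stage under the cohort's published statistical
structure. Its defaults *are* the study conditions:

* 35 initially-malignant / 23 initially-benign patients; terms to
  onset from normals 191.5 ± 127.5 and 485.7 ± 86.7 months, truncated
  below at 1 month (only means and SDs are published; truncation
  avoids non-physical values).
* Per-compartment, per-gene TaqMeth V from **zero-inflated
  log-normals** moment-matched to the published means ± SDs (tumor
  CDO1 16.90 ± 12.08, remnant mucosa CDO1 3.71 ± 4.74, and so on). A
  plain log-normal fits poorly where the SD exceeds the mean (e.g.
  remnant-mucosa Reprimo 0.62 ± 1.52); the zero mass also reflects
  genuinely undetected methylation. The zero mass pi0 is calibrated so
  the modelled fraction exceeding the diagnostic cut-offs matches the
  published exceedance proportions where those are printed (tumor and
  remnant mucosa), and is 0 elsewhere. pi0 has a feasibility ceiling
  s²/(m² + s²); unattainable targets get the closest feasible mass.
* A **Gaussian copula** couples the genes: correlation 0.6 among
  CDO1/HOPX/Reprimo, 0 to E-cadherin. "Close correlations" among the
  trio are reported without coefficients, so 0.6 is a configuration
  knob representing a strong rank correlation, not a claim.
* Both diagnosis groups draw remnant-mucosa methylation from the
  pooled parameters (no significant group difference is reported for
  the trio there); an optional mean-shift knob exists for sensitivity
  analysis.
* Biopsies: 43 specimens over 12 initially-malignant patients, lead
  times from a truncated normal targeting 83.6 ± 78.5 months, capped
  by each patient's own onset term. Gene values couple negatively to
  the lead time through the latent copula. The coupling strengths
  (CDO1 0.21, HOPX 0.31, Reprimo 0.54, E-cadherin 0.065) were
  calibrated once, by large-n simulation at design time, so the fitted
  value-on-months r² reproduces the published weak correlations
  (0.06 / 0.11 / 0.14 / 0.015): the zero-inflated log-normal transform
  attenuates latent correlation roughly threefold.
* Survival: exponential event times with hazard ratio 3 for composite
  stage III/IV (configurable), baseline OS hazard 0.012 per month
  (median ~58 months, a realistic figure for a mixed-stage gastric
  cancer cohort), relapse hazard 1.3 times the OS hazard capped at the
  observed OS time, censoring at 60 months. Categorical
  clinicopathological labels are drawn with the published marginal
  frequencies (sex 51:7, stage ≤II:≥III 46:12, etc.).

**What the generator does *not* emulate** — and hence what passing
tests do and do not show: it reproduces marginal moments, exceedance
fractions, rank correlations and group separations, not the joint
dependence of methylation on histology, *H. pylori* status or age that
real mucosa exhibits; biopsy series within a patient are exchangeable
draws rather than a monotone per-patient trajectory; survival is
exponential, so non-proportional hazards never arise. Tests passing on
this cohort validate the *computational machinery* under the published
summary statistics; they are not evidence about new patients.

## Numerical choices and degenerate inputs

* Candidate thresholds are the observed unique values, not midpoints
  (the published cut-offs look like observed measurements); scan ties
  break toward the larger threshold.
* Percents are reported to one decimal, rounding half away from zero
  (the clinical-table convention; base R rounds half to even).
* A degenerate log-rank risk table (e.g. every event at one shared
  time) has zero variance; the split carries no information and is
  reported as chi² = 0, p = 1.
* `anova_tukey` on groups with no variation at all returns F = 0,
  p = 1 rather than 0/0.
* Zero-hazard survival configurations yield infinite latent event
  times, hence universal censoring at the horizon.
* All randomness flows from a single integer seed; a fixed seed makes
  the whole pipeline byte-deterministic, which the manifest digests
  record.

## Problem sizes used in the test suite

Property suites run at the sizes that make their guarantees sharp but
cheap: brute-force scan equivalence at n ≤ 30 (where exhaustive
enumeration is exact), copula and moment recovery at n = 10⁴–10⁵,
parameter-recovery and null-calibration loops at 200–500 replicates,
and the propensity benchmark at 200 simulated cohorts of the study's
own size (n = 58). One caveat discovered in testing: for the
heaviest-tailed compartment cells the *SD estimator's own* sampling
error at n = 10⁵ exceeds 2% (the fourth moment of a log-normal with
sigma² ≈ 2 is enormous), so SD-recovery checks budget four analytic
standard errors computed from the closed-form fourth moment; means are
held to 2% everywhere.

## Known limitations

* Reported group sizes for the Reprimo biopsy split (15 + 18 = 33) do
  not match the 43 biopsies; the package treats partial panels as
  missing data and does not force that table to reproduce.
* The published "P < 0.0001" for the 77.1% vs 56.5% score-rate
  comparison is not reproducible from a 2×2 chi-squared of 27/35 vs
  13/23; the package computes the test it can justify and does not
  assert the printed bound.
* The methylation-only propensity AUC (0.7) depends on unpublished
  per-group mucosa distributions and is reported by the pipeline but
  not calibrated to.
* The minimum-p thresholds and in-sample AUCs are optimistic by
  construction; the permutation adjustment and cross-validated AUC
  are the honest companions and should be preferred for any new
  cohort.
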