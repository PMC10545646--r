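# Nonparametric signal-detection analysis of the rate-categorization task.
#
# Responses are scored against the 4-Hz ("slow") / 6-Hz ("fast") category
# structure: a hit is "slow" to a 4-Hz stimulus, a false alarm is "slow" to
# a 6-Hz stimulus.  Sensitivity A (an ROC-area-like index, 0.5 = chance)
# and decision criterion b (1 = neutral; b > 1 means mistaken "fast"
# responses outnumbered mistaken "slow" responses) are the distribution-free
# estimators of Zhang & Mueller (2005), appropriate here because the 4- and
# 6-Hz IPI sampling distributions have unequal variance at every nonzero
# noise level.

#' Apply trial exclusions
#'
#' Experiment 1: removes trials with no response and trials answered
#' prematurely (response time before the onset of the second pulse, i.e.
#' before any rate information was available).  Experiment 2: removes only
#' no-response trials; short-RT 2IFC trials are deliberately retained,
#' since the double pulse may legitimately be identified during the first
#' interval.
#'
#' @param trials A trial table from [simulate_dataset()] or
#'   [read_trials()].
#' @param experiment 1 or 2; defaults to the table's `experiment` column.
#' @return List with `trials` (the retained rows, with an
#'   `exclusion_reason` column equal to `"none"`) and `summary` (a tibble
#'   of counts and proportions per exclusion reason, including retained
#'   trials, so that counts conserve the input total).
#' @export
apply_exclusions <- function(trials, experiment = NULL) {
  if (is.null(experiment)) {
    experiment <- unique(trials$experiment)
  }
  if (length(experiment) != 1 || !experiment %in% c(1, 2)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  reason <- rep("none", nrow(trials))
  reason[trials$response == "none"] <- "no_response"
  if (experiment == 1) {
    first_ipi <- as.numeric(sub(";.*$", "", trials$ipi_sequence))
    second_onset <- PULSE_MS + first_ipi
    premature <- !is.na(trials$rt_ms) & trials$rt_ms < second_onset &
      reason == "none"
    reason[premature] <- "premature"
  }
  trials$exclusion_reason <- reason
  summary <- dplyr::count(
    tibble::tibble(exclusion_reason = factor(
      reason, levels = c("none", "no_response", "premature")
    )),
    .data$exclusion_reason, .drop = FALSE, name = "n_trials"
  )
  summary$proportion <- summary$n_trials / nrow(trials)
  list(
    trials = dplyr::filter(trials, .data$exclusion_reason == "none"),
    summary = summary
  )
}

#' Tabulate hits, misses, false alarms and correct rejections
#'
#' One row per subject x modality x noise cell.  Hit = "slow" response to
#' a 4-Hz stimulus; false alarm = "slow" response to a 6-Hz stimulus.
#'
#' @param trials An experiment-1 trial table after [apply_exclusions()].
#' @return Tibble with columns `subject_id`, `modality`, `noise_level`,
#'   `n_hit`, `n_miss`, `n_fa`, `n_cr`.
#' @export
tabulate_sdt <- function(trials) {
  if (!all(trials$experiment == 1)) {
    stop("signal-detection tabulation is defined for experiment 1 tables",
         call. = FALSE)
  }
  if (any(!trials$response %in% c("slow", "fast"))) {
    stop("table contains unresolved responses; run `apply_exclusions()` first",
         call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$modality,
                    .data$noise_level),
    n_hit = sum(.data$rate_hz == 4 & .data$response == "slow"),
    n_miss = sum(.data$rate_hz == 4 & .data$response == "fast"),
    n_fa = sum(.data$rate_hz == 6 & .data$response == "slow"),
    n_cr = sum(.data$rate_hz == 6 & .data$response == "fast"),
    .groups = "drop"
  )
}

#' Hit and false-alarm rates with boundary correction
#'
#' `H = n_hit / (n_hit + n_miss)`, `F = n_fa / (n_fa + n_cr)`.  Perfect
#' rates are pulled off the boundary: a rate of 0 becomes `1/(2N)` and a
#' rate of 1 becomes `1 - 1/(2N)`, with N the number of trials of that
#' stimulus type in the cell.  Vectorised.
#'
#' @param n_hit,n_miss,n_fa,n_cr Cell counts.
#' @return Tibble with columns `H` and `F`.
#' @export
rates_from_counts <- function(n_hit, n_miss, n_fa, n_cr) {
  n_signal <- n_hit + n_miss
  n_noise <- n_fa + n_cr
  if (any(n_signal == 0) || any(n_noise == 0)) {
    stop("cell with no signal or no noise trials", call. = FALSE)
  }
  correct_rate <- function(x, n) {
    pmin(pmax(x / n, 1 / (2 * n)), 1 - 1 / (2 * n))
  }
  tibble::tibble(
    H = correct_rate(n_hit, n_signal),
    F = correct_rate(n_fa, n_noise)
  )
}

check_rates <- function(H, F) {
  if (any(H <= 0 | H >= 1 | F <= 0 | F >= 1)) {
    stop("H and F must lie strictly in (0, 1); apply the boundary correction",
         call. = FALSE)
  }
}

# Zhang & Mueller (2005) estimators, defined for H >= F; the three branches
# partition the unit square by which side of 1/2 the rates fall on.
zm_A_hf <- function(H, F) {
  dplyr::case_when(
    F <= 0.5 & H >= 0.5 ~ 0.75 + (H - F) / 4 - F * (1 - H),
    H < 0.5             ~ 0.75 + (H - F) / 4 - F / (4 * H),
    TRUE                ~ 0.75 + (H - F) / 4 - (1 - H) / (4 * (1 - F))
  )
}

zm_b_hf <- function(H, F) {
  dplyr::case_when(
    F <= 0.5 & H >= 0.5 ~ (5 - 4 * H) / (1 + 4 * F),
    H < 0.5             ~ (H^2 + H) / (H^2 + F),
    TRUE                ~ ((1 - F)^2 + (1 - H)) / ((1 - F)^2 + (1 - F))
  )
}

#' Nonparametric sensitivity A
#'
#' Distribution-free sensitivity index in \[0, 1\] (0.5 = chance),
#' estimated from a single (H, F) pair.  Below-chance cells (H < F) are
#' handled by reflection: `A(H, F) = 1 - A(F, H)`.  Vectorised.
#'
#' @param H,F Corrected hit and false-alarm rates, strictly inside (0, 1).
#' @return Sensitivity A.
#' @examples
#' zm_sensitivity(0.9, 0.1) # 0.94
#' @export
zm_sensitivity <- function(H, F) {
  check_rates(H, F)
  ifelse(H >= F, zm_A_hf(H, F), 1 - zm_A_hf(F, H))
}

#' Nonparametric decision criterion b
#'
#' Distribution-free criterion-location index (> 0).  b = 1 is a neutral
#' criterion (both misattribution errors equally likely); under the
#' hit = "slow"|4 Hz scoring, b > 1 means mistaken "fast" responses
#' exceeded mistaken "slow" responses and b < 1 the reverse.  Below-chance
#' cells (H < F) are handled by swapping the rates and inverting:
#' `b(H, F) = 1 / b(F, H)`.  Vectorised.
#'
#' @inheritParams zm_sensitivity
#' @return Criterion b.
#' @examples
#' zm_bias(0.75, 0.25) # 1
#' @export
zm_bias <- function(H, F) {
  check_rates(H, F)
  ifelse(H >= F, zm_b_hf(H, F), 1 / zm_b_hf(F, H))
}

#' Subject-level sensitivity and criterion estimates
#'
#' The full experiment-1 analysis path: exclusions, cell tabulation,
#' boundary-corrected rates, and the A / b estimators, one row per
#' subject x modality x noise cell (10 cells per subject).
#'
#' @param trials An experiment-1 trial table (exclusions are applied
#'   internally if an `exclusion_reason` column is absent).
#' @return Tibble with `subject_id`, `modality`, `noise_level`, cell
#'   counts, `H`, `F`, `A`, `b`.
#' @export
estimate_sdt <- function(trials) {
  if (!"exclusion_reason" %in% names(trials)) {
    trials <- apply_exclusions(trials, experiment = 1)$trials
  }
  counts <- tabulate_sdt(trials)
  rates <- rates_from_counts(counts$n_hit, counts$n_miss,
                             counts$n_fa, counts$n_cr)
  dplyr::mutate(counts,
    H = rates$H,
    F = rates$F,
    A = zm_sensitivity(rates$H, rates$F),
    b = zm_bias(rates$H, rates$F)
  )
}
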