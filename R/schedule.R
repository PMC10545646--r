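# Experiment schedules: the complete, balanced trial plans for the
# rate-categorization experiment (Exp 1) and the 2IFC gap-detection
# experiment (Exp 2).

GAP_SET_MS <- c(2, 4, 8, 16, 32)
MODALITIES_EXP1 <- c("V", "T")
MODALITIES_EXP2 <- c("V", "T", "VT")

# Fixed trial-timing metadata, recorded on schedules for completeness.
# None of it affects the analyses.
exp1_timing <- function() {
  list(alert_tone_ms = 500, pre_stimulus_delay_ms = 500,
       response_window_s = 8, iti_s = 1)
}
exp2_timing <- function() {
  list(alert_tone_ms = 200, pre_stimulus_delay_ms = 800,
       inter_stimulus_interval_s = 1, response_window_s = 2, iti_s = 0.5)
}

new_schedule <- function(trials, experiment, timing, seed) {
  structure(
    trials,
    experiment = experiment,
    timing = timing,
    seed = seed,
    class = c("experiment_schedule", class(trials))
  )
}

#' @export
print.experiment_schedule <- function(x, ...) {
  cat(sprintf("<experiment_schedule> experiment %d, %d trials, %d blocks\n",
              attr(x, "experiment"), nrow(x), max(x$block)))
  NextMethod()
}

maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Build the rate-categorization trial schedule
#'
#' 16 test blocks of 50 trials (800 trials).  Blocks alternate between
#' visual (V) and tactile (T) stimulation; the starting modality is the
#' between-subject counterbalance arm.  Within every block the 10 stimulus
#' cells (2 rates x 5 noise levels) each appear exactly 5 times in shuffled
#' order, so each modality x rate x noise cell receives 40 trials overall
#' and exactly 20% of trials are isochronous (0% noise).
#'
#' @param first_modality Counterbalance arm: modality of block 1, `"V"` or
#'   `"T"`.
#' @param seed Optional integer seed; when supplied the schedule is
#'   reproducible bit-for-bit (the global RNG state is left untouched).
#' @return A tibble of class `experiment_schedule` with columns
#'   `experiment`, `block`, `trial_in_block`, `trial_index`, `modality`,
#'   `rate_hz`, `noise_level`.  Trial-timing constants are attached as the
#'   `timing` attribute.
#' @examples
#' sched <- build_exp1_schedule(seed = 1)
#' table(sched$modality, sched$noise_level)
#' @export
build_exp1_schedule <- function(first_modality = c("V", "T"), seed = NULL) {
  first_modality <- match.arg(first_modality)
  block_modality <- rep_len(
    if (first_modality == "V") c("V", "T") else c("T", "V"), 16L
  )
  cell <- tidyr::expand_grid(
    rate_hz = c(4, 6),
    noise_level = NOISE_LEVELS,
    rep = 1:5
  )
  trials <- maybe_with_seed(seed, {
    purrr::map_dfr(1:16, function(b) {
      ord <- sample.int(nrow(cell))
      tibble::tibble(
        block = b,
        trial_in_block = seq_len(nrow(cell)),
        modality = block_modality[b],
        rate_hz = cell$rate_hz[ord],
        noise_level = cell$noise_level[ord]
      )
    })
  })
  trials <- dplyr::mutate(trials,
                          experiment = 1L,
                          trial_index = dplyr::row_number(),
                          .before = 1)
  new_schedule(trials, 1L, exp1_timing(), seed)
}

#' Build the 2IFC gap-detection trial schedule
#'
#' 9 test blocks of 50 trials (450 trials), block-randomized by modality
#' with exactly 3 blocks per modality (V, T, VT).  Within every block each
#' of the 5 gap durations \{2, 4, 8, 16, 32\} ms appears 10 times in
#' shuffled order, so each modality x gap cell receives 30 trials.  Each
#' trial carries a randomized `dp_first` flag (whether the double-pulse
#' stimulus leads) and the single-pulse duration `sp_duration_ms`
#' = 100 + gap, which equates total stimulus energy across the interval
#' pair.
#'
#' @inheritParams build_exp1_schedule
#' @return A tibble of class `experiment_schedule` with columns
#'   `experiment`, `block`, `trial_in_block`, `trial_index`, `modality`,
#'   `gap_ms`, `dp_first`, `sp_duration_ms`.
#' @export
build_exp2_schedule <- function(seed = NULL) {
  trials <- maybe_with_seed(seed, {
    block_modality <- sample(rep(MODALITIES_EXP2, each = 3L))
    purrr::map_dfr(1:9, function(b) {
      gaps <- sample(rep(GAP_SET_MS, each = 10L))
      tibble::tibble(
        block = b,
        trial_in_block = seq_along(gaps),
        modality = block_modality[b],
        gap_ms = gaps,
        dp_first = sample(c(TRUE, FALSE), length(gaps), replace = TRUE)
      )
    })
  })
  trials <- dplyr::mutate(trials,
                          experiment = 2L,
                          trial_index = dplyr::row_number(),
                          sp_duration_ms = 100 + .data$gap_ms,
                          .before = 1)
  trials <- dplyr::relocate(trials, "experiment", "block", "trial_in_block",
                            "trial_index", "modality", "gap_ms", "dp_first",
                            "sp_duration_ms")
  new_schedule(trials, 2L, exp2_timing(), seed)
}
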