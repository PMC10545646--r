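# Shared fixtures: deterministic observers and small simulated datasets.

noiseless_rate_observer <- function(criterion_ms = 158) {
  rate_observer_params(
    sigma_sense_ms = c(V = 0, T = 0),
    persistence_ms = c(V = 0, T = 0),
    criterion_ms = criterion_ms,
    lapse = 0,
    subject_cv = 0
  )
}

lapse_free_gap_observer <- function(...) {
  gap_observer_params(lapse = 0, subject_cv = 0, ...)
}

# small exp-1 table built by hand for exclusion / tabulation tests
handmade_exp1_trials <- function() {
  tibble::tibble(
    subject_id = "S01",
    experiment = 1L,
    block = 1L,
    trial_index = 1:6,
    modality = "T",
    rate_hz = c(4, 4, 6, 6, 4, 6),
    noise_level = 0,
    ipi_sequence = paste(rep(200, 9), collapse = ";"),
    response = c("slow", "fast", "slow", "fast", "none", "slow"),
    rt_ms = c(1500, 150, 1200, 900, NA, 2000),
    pulses_presented = 10L
  )
}
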