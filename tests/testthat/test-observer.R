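test_that("the noiseless observer categorizes rate by the criterion alone", {
  obs <- noiseless_rate_observer(criterion_ms = 158)
  s4 <- generate_rate_sequence(rate_stimulus_spec(4, 0), 10)
  s6 <- generate_rate_sequence(rate_stimulus_spec(6, 0), 10)
  for (i in 1:5) {
    expect_equal(simulate_rate_response(s4, "V", obs)$response, "slow")
    expect_equal(simulate_rate_response(s6, "T", obs)$response, "fast")
  }
  expect_error(
    simulate_rate_response(
      generate_rate_sequence(rate_stimulus_spec(4, 0), 1), "V", obs
    ),
    "at least 2 pulses"
  )
})

test_that("sensory persistence shortens perceived IPIs and flips decisions", {
  # 25-ms visual persistence moves a 4-Hz train (200-ms IPIs) to a
  # perceived 175 ms; a criterion above that now yields "fast"
  obs <- noiseless_rate_observer(criterion_ms = 185)
  obs$persistence_ms <- c(V = 25, T = 0)
  s4 <- generate_rate_sequence(rate_stimulus_spec(4, 0), 10)
  expect_equal(simulate_rate_response(s4, "V", obs)$response, "fast")
  expect_equal(simulate_rate_response(s4, "T", obs)$response, "slow")
})

test_that("increasing sensory noise lowers sensitivity A", {
  sched <- build_exp1_schedule(seed = 2)
  a_of_sigma <- function(sig) {
    p <- rate_observer_params(
      sigma_sense_ms = c(V = sig, T = sig),
      persistence_ms = c(V = 0, T = 0),
      criterion_ms = 158, lapse = 0, subject_cv = 0
    )
    trials <- simulate_dataset(sched, p, n_subjects = 2, seed = 99,
                               no_response_rate = 0, premature_rate = 0)
    mean(estimate_sdt(trials)$A)
  }
  a <- vapply(c(20, 60, 120), a_of_sigma, numeric(1))
  expect_true(all(diff(a) < 0))
})

test_that("visual persistence produces a 'fast' bias (b > 1) for V but not T", {
  # matched sensory noise; only persistence differs between modalities
  p <- rate_observer_params(
    sigma_sense_ms = c(V = 35, T = 35),
    persistence_ms = c(V = 40, T = 5),
    criterion_ms = 153, lapse = 0, subject_cv = 0
  )
  sched <- build_exp1_schedule(seed = 4)
  trials <- simulate_dataset(sched, p, n_subjects = 10, seed = 123,
                             no_response_rate = 0, premature_rate = 0)
  est <- estimate_sdt(trials)
  b_mod <- tapply(est$b, est$modality, mean)
  expect_gt(b_mod[["V"]], 1.3)
  expect_lt(abs(b_mod[["T"]] - 1), 0.2)
  # the same asymmetry shows as more errors on 4-Hz than 6-Hz visual trials
  v4 <- trials$modality == "V" & trials$rate_hz == 4
  v6 <- trials$modality == "V" & trials$rate_hz == 6
  err4 <- mean(trials$response[v4] != "slow")
  err6 <- mean(trials$response[v6] != "fast")
  expect_gt(err4, err6)
})

test_that("gap_pc has the stated asymptotes, midpoint and mixture limits", {
  p <- lapse_free_gap_observer()
  expect_equal(gap_pc(p$tau_ms[["T"]], "T", p), 0.75)
  expect_equal(gap_pc(p$tau_ms[["V"]], "V", p), 0.75)
  expect_equal(gap_pc(1e4, "T", p), 1.0)
  expect_equal(gap_pc(0, "V", p), 0.5, tolerance = 1e-4)
  # degenerate mixture: full tactile reliance reduces VT to T
  p1 <- gap_observer_params(tactile_reliance = 1, lapse = 0, subject_cv = 0)
  gaps <- seq(0, 40, by = 0.5)
  expect_equal(gap_pc(gaps, "VT", p1), gap_pc(gaps, "T", p1))
  expect_error(gap_pc(-1, "T", p), "non-negative")
})

test_that("gap_pc is non-decreasing in gap duration for varied parameters", {
  gaps <- seq(0, 64, by = 0.25)
  cases <- list(
    gap_observer_params(),
    gap_observer_params(tau_ms = c(V = 30, T = 2), slope_ms = c(V = 10, T = 1)),
    gap_observer_params(lapse = 0.1, tactile_reliance = 0.3)
  )
  for (p in cases) {
    for (m in c("V", "T", "VT")) {
      expect_true(all(diff(gap_pc(gaps, m, p)) >= 0))
    }
  }
})

test_that("population-average curve reduces to the subject curve when homogeneous", {
  p0 <- gap_observer_params(subject_cv = 0)
  gaps <- c(2, 4, 8, 16, 32)
  expect_equal(gap_pc_population(gaps, "VT", p0), gap_pc(gaps, "VT", p0))
  # with heterogeneity the population curve is a flattened version:
  # still monotone, same 0.5 floor
  p <- gap_observer_params(subject_cv = 0.7)
  pp <- gap_pc_population(seq(0, 40, by = 1), "T", p)
  expect_true(all(diff(pp) >= 0))
  expect_true(all(pp >= 0.5 & pp <= 1))
})

test_that("simulated gap trials hit their generating probability", {
  p <- lapse_free_gap_observer()
  # supra-threshold gap: always correct
  big <- replicate(50, simulate_gap_trial(1e3, "T", dp_first = TRUE, p)$correct)
  expect_true(all(big))
  # zero-information gap on the visual channel: guess rate 0.5
  hits <- withr::with_seed(8, {
    mean(replicate(1e4, simulate_gap_trial(0, "V", dp_first = FALSE, p)$correct))
  })
  expect_lt(abs(hits - 0.5), 3 * sqrt(0.25 / 1e4))
  # reported choice is consistent with the stimulus-order flag
  tr <- simulate_gap_trial(1e3, "T", dp_first = FALSE, p)
  expect_equal(tr$choice, "second")
})

test_that("simulate_dataset yields one row per subject x trial, reproducibly", {
  sched1 <- build_exp1_schedule(seed = 10)
  p <- rate_observer_params()
  tab <- simulate_dataset(sched1, p, n_subjects = 28, seed = 21)
  expect_equal(nrow(tab), 28 * 800)
  expect_identical(tab, simulate_dataset(sched1, p, n_subjects = 28, seed = 21))
  # no premature trials when the premature rate is zero
  clean <- simulate_dataset(sched1, p, n_subjects = 1, seed = 5,
                            no_response_rate = 0, premature_rate = 0)
  excl <- apply_exclusions(clean, experiment = 1)
  expect_equal(sum(excl$summary$n_trials[excl$summary$exclusion_reason != "none"]), 0)
  # parameter class must match the schedule's experiment
  expect_error(
    simulate_dataset(sched1, gap_observer_params(), 1),
    "rate_observer_params"
  )
  expect_error(
    simulate_dataset(build_exp2_schedule(seed = 1), p, 1),
    "gap_observer_params"
  )
})
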