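test_that("exclusion rules differ between the two experiments as intended", {
  tab <- handmade_exp1_trials()
  res <- apply_exclusions(tab, experiment = 1)
  # row 5 missed, row 2 answered at 150 ms before the second pulse at 250 ms
  expect_equal(nrow(res$trials), 4)
  expect_equal(
    res$summary$n_trials[res$summary$exclusion_reason == "no_response"], 1
  )
  expect_equal(
    res$summary$n_trials[res$summary$exclusion_reason == "premature"], 1
  )
  # accounting conserves trials
  expect_equal(sum(res$summary$n_trials), nrow(tab))
  expect_equal(sum(res$summary$proportion), 1)

  # the 2IFC task retains short-RT trials: the double pulse can be
  # identified during the first interval
  tab2 <- tibble::tibble(
    subject_id = "S01", experiment = 2L, block = 1L, trial_index = 1:3,
    modality = "VT", gap_ms = 8, dp_first = TRUE, sp_duration_ms = 108,
    response = c("first", "none", "second"),
    correct = c(TRUE, NA, FALSE), rt_ms = c(80, NA, 700)
  )
  res2 <- apply_exclusions(tab2, experiment = 2)
  expect_equal(nrow(res2$trials), 2)
  expect_true(80 %in% res2$trials$rt_ms)
  expect_error(apply_exclusions(tab, experiment = 3), "must be 1 or 2")
})

test_that("hit/false-alarm tabulation follows the slow|4Hz scoring", {
  tab <- handmade_exp1_trials()
  kept <- apply_exclusions(tab, experiment = 1)$trials
  counts <- tabulate_sdt(kept)
  expect_equal(counts$n_hit, 1)   # slow response to 4 Hz
  expect_equal(counts$n_miss, 0)
  expect_equal(counts$n_fa, 2)    # slow responses to 6 Hz
  expect_equal(counts$n_cr, 1)
  expect_error(tabulate_sdt(dplyr::mutate(kept, experiment = 2)),
               "experiment 1")
})

test_that("rates are boundary-corrected by 1/(2N)", {
  r <- rates_from_counts(30, 10, 8, 32)
  expect_equal(r$H, 0.75)
  expect_equal(r$F, 0.20)
  perfect <- rates_from_counts(40, 0, 0, 40)
  expect_equal(perfect$H, 1 - 1 / 80)
  expect_equal(perfect$F, 1 / 80)
  even <- rates_from_counts(20, 20, 20, 20)
  expect_equal(even$H, 0.5)
  expect_equal(even$F, 0.5)
  expect_error(rates_from_counts(0, 0, 5, 5), "no signal")
})

test_that("sensitivity and criterion match their closed forms", {
  expect_equal(zm_sensitivity(0.5, 0.5), 0.5)
  expect_equal(zm_sensitivity(0.9, 0.1), 0.94)
  expect_equal(zm_sensitivity(0.3, 0.3), 0.5)
  expect_equal(zm_bias(0.75, 0.25), 1.0)
  expect_equal(zm_bias(0.8, 0.1), 1.8 / 1.4)
  expect_equal(zm_bias(0.4, 0.2), 0.56 / 0.36)
  expect_error(zm_sensitivity(1, 0.5), "strictly")
  expect_error(zm_bias(0.5, 0), "strictly")
})

test_that("A = 0.5 on the chance diagonal and b = 1 at equal error rates", {
  h <- seq(0.01, 0.99, by = 0.01)
  expect_equal(zm_sensitivity(h, h), rep(0.5, length(h)))
  h2 <- seq(0.501, 0.999, by = 0.002)
  expect_equal(zm_bias(h2, 1 - h2), rep(1, length(h2)))
})

test_that("A and b are continuous across the branch boundaries", {
  eps <- 1e-9
  probe <- seq(0.05, 0.95, by = 0.05)
  # H crossing 0.5 (with F below both)
  f_lo <- probe[probe < 0.5]
  expect_equal(zm_sensitivity(0.5 + eps, f_lo), zm_sensitivity(0.5 - eps, f_lo),
               tolerance = 1e-7)
  expect_equal(zm_bias(0.5 + eps, f_lo), zm_bias(0.5 - eps, f_lo),
               tolerance = 1e-7)
  # F crossing 0.5 (with H above both)
  h_hi <- probe[probe > 0.5]
  expect_equal(zm_sensitivity(h_hi, 0.5 + eps), zm_sensitivity(h_hi, 0.5 - eps),
               tolerance = 1e-7)
  expect_equal(zm_bias(h_hi, 0.5 + eps), zm_bias(h_hi, 0.5 - eps),
               tolerance = 1e-7)
})

test_that("A is monotone in H and F; b signals the dominant error type", {
  grid <- expand.grid(H = seq(0.02, 0.98, by = 0.02),
                      F = seq(0.02, 0.98, by = 0.02))
  # strictly above-chance cells: on the H = F diagonal b = 1 exactly even
  # though one error type can still be the more frequent
  grid <- grid[grid$H > grid$F, ]
  A <- zm_sensitivity(grid$H, grid$F)
  b <- zm_bias(grid$H, grid$F)
  expect_true(all(A >= 0.5 - 1e-12 & A <= 1))
  expect_true(all(b > 0))
  # monotone: raising H (by one grid step) never lowers A
  A_up <- zm_sensitivity(pmin(grid$H + 0.02, 0.99), grid$F)
  expect_true(all(A_up - A >= -1e-12))
  A_fup <- zm_sensitivity(grid$H, pmin(grid$F + 0.02, grid$H))
  expect_true(all(A_fup - A <= 1e-12))
  # b > 1 iff misses dominate ((1-H) > F), b < 1 iff false alarms dominate
  misses_dominate <- (1 - grid$H) - grid$F > 1e-9
  fas_dominate <- (1 - grid$H) - grid$F < -1e-9
  expect_true(all(b[misses_dominate] > 1))
  expect_true(all(b[fas_dominate] < 1))
})

test_that("below-chance cells are handled by reflection and inversion", {
  H <- c(0.2, 0.4, 0.6)
  F <- c(0.7, 0.9, 0.8)
  expect_equal(zm_sensitivity(H, F), 1 - zm_sensitivity(F, H))
  expect_equal(zm_bias(H, F), 1 / zm_bias(F, H))
})

test_that("an observer who misses more than it false-alarms shows b > 1", {
  # criterion well above the tactile midpoint: many 4-Hz trials called
  # "fast", few 6-Hz trials called "slow"
  p <- rate_observer_params(
    sigma_sense_ms = c(V = 40, T = 40),
    persistence_ms = c(V = 0, T = 0),
    criterion_ms = 185, lapse = 0, subject_cv = 0
  )
  sched <- build_exp1_schedule(seed = 6)
  trials <- simulate_dataset(sched, p, n_subjects = 6, seed = 31,
                             no_response_rate = 0, premature_rate = 0)
  est <- estimate_sdt(trials)
  counts <- tabulate_sdt(trials)
  expect_gt(sum(counts$n_miss), sum(counts$n_fa))
  expect_gt(mean(est$b), 1)
})

test_that("estimate_sdt yields 10 cells per subject with coherent values", {
  sched <- build_exp1_schedule(seed = 12)
  trials <- simulate_dataset(sched, rate_observer_params(), 3, seed = 13)
  est <- estimate_sdt(trials)
  expect_equal(nrow(est), 3 * 10)
  expect_true(all(est$A >= 0 & est$A <= 1))
  expect_true(all(est$b > 0))
  expect_true(all(est$n_hit + est$n_miss <= 40))
})
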