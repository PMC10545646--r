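# Synthetic observers.
#
# The pipeline's analyses need trial-level data with the statistical
# structure the real tasks produce.  Two minimal generative observers
# provide it:
#
# * Rate task: each inter-pulse interval is perceived as
#   max(0, IPI - persistence) + Gaussian sensory noise; the decision
#   statistic is a geometrically decaying weighted mean of the perceived
#   IPIs (earlier intervals weigh more), compared against a criterion in
#   ms.  Visual persistence exceeding tactile persistence shortens
#   perceived visual IPIs, producing the "fast" bias (criterion b > 1) on
#   visual trials; larger visual sensory noise produces the tactile
#   sensitivity advantage.
#
# * Gap task: each unimodal channel has a Gaussian-CDF psychometric
#   function with guess rate 0.5; on bimodal trials the judgment comes
#   from the tactile channel alone with probability `tactile_reliance`
#   (a probability mixture, not optimal integration: bimodal thresholds
#   slightly *worse* than tactile cannot arise from variance-weighted
#   averaging).

#' Parameters of the synthetic rate-categorization observer
#'
#' @param sigma_sense_ms Named numeric (`V`, `T`): SD in ms of the additive
#'   perceptual noise on each perceived IPI.
#' @param persistence_ms Named numeric (`V`, `T`): ms by which sensory
#'   persistence shortens each perceived empty interval.  Must be below the
#'   nominal 6-Hz IPI (116 ms).
#' @param criterion_ms Cutoff on the weighted mean perceived IPI: respond
#'   "slow" when the statistic exceeds it.
#' @param lapse Probability of a uniformly random response, in \[0, 0.1\].
#' @param weight_decay Geometric decay of per-interval evidence weights
#'   (interval i gets weight `weight_decay^(i-1)`), in (0, 1].
#' @param subject_cv Between-subject coefficient of variation: when
#'   simulating several subjects, each subject's sensory-noise SDs are
#'   scaled by a shared lognormal multiplier with mean 1 and this CV, so
#'   subjects differ in overall temporal acuity.
#'
#' @details Defaults are calibrated so that the qualitative modality
#'   patterns of interest emerge at the design's trial counts: tactile
#'   sensitivity (A) above visual at every noise level, A declining with
#'   noise, a visual "fast" bias (b > 1) at low noise, and a near-neutral
#'   tactile criterion.
#' @return Object of class `rate_observer_params`.
#' @export
rate_observer_params <- function(sigma_sense_ms = c(V = 60, T = 35),
                                 persistence_ms = c(V = 25, T = 5),
                                 criterion_ms = 158,
                                 lapse = 0.02,
                                 weight_decay = 0.6,
                                 subject_cv = 0.15) {
  stopifnot(
    all(c("V", "T") %in% names(sigma_sense_ms)),
    all(c("V", "T") %in% names(persistence_ms)),
    all(sigma_sense_ms >= 0),
    all(persistence_ms >= 0), all(persistence_ms < 116),
    lapse >= 0, lapse <= 0.1,
    weight_decay > 0, weight_decay <= 1,
    criterion_ms > 0,
    subject_cv >= 0
  )
  structure(
    list(
      sigma_sense_ms = sigma_sense_ms[c("V", "T")],
      persistence_ms = persistence_ms[c("V", "T")],
      criterion_ms = criterion_ms,
      lapse = lapse,
      weight_decay = weight_decay,
      subject_cv = subject_cv
    ),
    class = "rate_observer_params"
  )
}

# Lognormal multipliers with mean 1 and coefficient of variation cv.
subject_multipliers <- function(n, cv) {
  if (cv == 0) return(rep.int(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Parameters of the synthetic gap-detection observer
#'
#' @param tau_ms Named numeric (`V`, `T`): gap duration in ms at which the
#'   channel's discriminability reaches d' = 1 (the midpoint of its
#'   psychometric function).  Defaults keep the tactile threshold about 3x
#'   smaller than the visual one.
#' @param slope_ms Named numeric (`V`, `T`): SD in ms of the channel's
#'   internal noise (the Gaussian-CDF spread of its psychometric function).
#' @param lapse Probability of a uniformly random response.
#' @param tactile_reliance Probability that a bimodal (VT) trial is judged
#'   by the tactile channel alone, in \[0, 1\].
#' @param subject_cv Between-subject coefficient of variation: each
#'   simulated subject's `tau_ms` values are scaled by lognormal
#'   multipliers with mean 1 and this CV, drawn independently per channel.
#'   Subjects therefore differ in temporal acuity, and because the bimodal
#'   judgment rides mostly on the tactile channel, subject-level tactile
#'   and bimodal accuracies are correlated while visual and bimodal
#'   accuracies are only weakly so.
#' @return Object of class `gap_observer_params`.
#' @export
gap_observer_params <- function(tau_ms = c(V = 15.5, T = 5),
                                slope_ms = c(V = 4, T = 4),
                                lapse = 0.02,
                                tactile_reliance = 0.9,
                                subject_cv = 0.7) {
  stopifnot(
    all(c("V", "T") %in% names(tau_ms)), all(tau_ms > 0),
    all(c("V", "T") %in% names(slope_ms)), all(slope_ms > 0),
    lapse >= 0, lapse <= 0.1,
    tactile_reliance >= 0, tactile_reliance <= 1,
    subject_cv >= 0
  )
  structure(
    list(
      tau_ms = tau_ms[c("V", "T")],
      slope_ms = slope_ms[c("V", "T")],
      lapse = lapse,
      tactile_reliance = tactile_reliance,
      subject_cv = subject_cv
    ),
    class = "gap_observer_params"
  )
}

#' Population-average psychometric curve of the gap observer
#'
#' Marginalises [gap_pc()] over the between-subject distribution of
#' `tau_ms` multipliers (lognormal, mean 1, CV `subject_cv`) by numerical
#' integration.  This is the expected group-level performance curve when
#' many subjects are pooled, and serves as the generating reference for
#' threshold-recovery checks.
#'
#' @inheritParams gap_pc
#' @return Expected probability correct, vectorised over `gap_ms`.
#' @export
gap_pc_population <- function(gap_ms, modality = c("V", "T", "VT"), params) {
  stopifnot(inherits(params, "gap_observer_params"))
  modality <- match.arg(modality)
  if (params$subject_cv == 0) return(gap_pc(gap_ms, modality, params))
  s <- sqrt(log(1 + params$subject_cv^2))
  channel_mean <- function(m, x) {
    # E over multiplier M = exp(s Z - s^2/2), Z ~ N(0,1)
    vapply(x, function(xi) {
      stats::integrate(function(z) {
        tau <- params$tau_ms[m] * exp(s * z - s^2 / 2)
        (0.5 + (0.5 - params$lapse) *
           stats::pnorm((xi - tau) / params$slope_ms[m])) * stats::dnorm(z)
      }, -8, 8, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  p <- switch(modality,
    V = channel_mean("V", gap_ms),
    T = channel_mean("T", gap_ms),
    VT = params$tactile_reliance * channel_mean("T", gap_ms) +
      (1 - params$tactile_reliance) * channel_mean("V", gap_ms)
  )
  unname(p)
}

# Vectorised core of the rate observer: one row of `ipi_matrix` per trial.
# Returns character vector of "slow"/"fast".
rate_responses_from_ipis <- function(ipi_matrix, modality, params) {
  stopifnot(inherits(params, "rate_observer_params"))
  n_trials <- nrow(ipi_matrix)
  n_ipis <- ncol(ipi_matrix)
  rho <- params$persistence_ms[modality]
  sigma <- params$sigma_sense_ms[modality]
  perceived <- pmax(0, ipi_matrix - rho) +
    matrix(stats::rnorm(n_trials * n_ipis, 0, 1), n_trials) * sigma
  w <- params$weight_decay^(seq_len(n_ipis) - 1)
  statistic <- as.vector(perceived %*% w) / sum(w)
  resp <- ifelse(statistic > params$criterion_ms, "slow", "fast")
  lapsed <- stats::runif(n_trials) < params$lapse
  if (any(lapsed)) {
    resp[lapsed] <- sample(c("slow", "fast"), sum(lapsed), replace = TRUE)
  }
  resp
}

#' Simulate one rate-categorization response
#'
#' Applies the synthetic observer's decision rule to a single pulse train:
#' with probability `lapse` a fair random response; otherwise each IPI is
#' perceived as `max(0, IPI - persistence) + noise`, the perceived IPIs are
#' combined by a geometrically weighted mean, and the response is "slow"
#' iff the statistic exceeds the criterion.
#'
#' @param seq A [generate_rate_sequence()] pulse train with at least 2
#'   pulses.
#' @param modality `"V"` or `"T"`.
#' @param params A [rate_observer_params()].
#' @return A list with `response` (`"slow"` or `"fast"`) and
#'   `pulses_observed` (the observer integrates the full train, so the
#'   number of pulses in `seq`).
#' @export
simulate_rate_response <- function(seq, modality = c("V", "T"), params) {
  stopifnot(inherits(seq, "pulse_sequence"))
  modality <- match.arg(modality)
  if (length(seq$ipis_ms) < 1) {
    stop("rate response requires a sequence with at least 2 pulses",
         call. = FALSE)
  }
  resp <- rate_responses_from_ipis(matrix(seq$ipis_ms, nrow = 1),
                                   modality, params)
  list(response = resp, pulses_observed = length(seq$pulse_onsets_ms))
}

#' Probability correct of the synthetic gap observer
#'
#' Unimodal channels follow `p_m(x) = 0.5 + (0.5 - lapse) * pnorm((x -
#' tau_m) / slope_m)`; bimodal trials are a probability mixture
#' `p_VT = pi * p_T + (1 - pi) * p_V` with `pi = tactile_reliance`.
#'
#' @param gap_ms Gap duration(s) in ms, >= 0.
#' @param modality `"V"`, `"T"` or `"VT"`.
#' @param params A [gap_observer_params()].
#' @return Probability correct in \[0.5, 1\], vectorised over `gap_ms`.
#' @export
gap_pc <- function(gap_ms, modality = c("V", "T", "VT"), params) {
  stopifnot(inherits(params, "gap_observer_params"))
  modality <- match.arg(modality)
  if (any(gap_ms < 0)) stop("`gap_ms` must be non-negative", call. = FALSE)
  channel <- function(m) {
    0.5 + (0.5 - params$lapse) *
      stats::pnorm((gap_ms - params$tau_ms[m]) / params$slope_ms[m])
  }
  p <- switch(modality,
    V = channel("V"),
    T = channel("T"),
    VT = params$tactile_reliance * channel("T") +
      (1 - params$tactile_reliance) * channel("V")
  )
  unname(p)
}

#' Simulate one 2IFC gap-detection trial
#'
#' The trial is answered correctly with probability
#' [gap_pc()]`(gap_ms, modality)`, independently across trials; the
#' reported choice ("first"/"second" interval contained the double pulse)
#' is made consistent with the trial's `dp_first` flag.
#'
#' @param gap_ms Gap duration in ms.
#' @param modality `"V"`, `"T"` or `"VT"`.
#' @param dp_first Logical: does the double-pulse stimulus lead?
#' @param params A [gap_observer_params()].
#' @return List with `choice` (`"first"`/`"second"`) and `correct`
#'   (logical).
#' @export
simulate_gap_trial <- function(gap_ms, modality, dp_first, params) {
  p <- gap_pc(gap_ms, modality, params)
  correct <- stats::runif(1) < p
  # the correct choice names the interval that held the double pulse
  choice <- if (correct == dp_first) "first" else "second"
  list(choice = choice, correct = correct)
}

response_times_exp1 <- function(n) {
  # plausible decision times (ms from sequence onset); analysis ignores
  # everything but the premature-response rule
  round(stats::rlnorm(n, log(1600), 0.25))
}

#' Simulate a full trial table from a schedule
#'
#' Runs `n_subjects` independent synthetic observers through an experiment
#' schedule and returns a tidy trial table, one row per subject x trial --
#' the interchange format consumed by [apply_exclusions()],
#' [estimate_sdt()] and [fit_gap_thresholds()].  Stimulus jitter is
#' re-sampled independently for every subject; the schedule contributes the
#' balanced design and trial order.
#'
#' A small fraction of trials is marked as missed (`response = "none"`)
#' and, for the rate experiment, as answered prematurely (response time
#' before the second pulse's onset), so that downstream exclusion logic is
#' exercised.
#'
#' @param schedule An [build_exp1_schedule()] or [build_exp2_schedule()]
#'   schedule.
#' @param params Observer parameters matching the schedule's experiment
#'   ([rate_observer_params()] for experiment 1, [gap_observer_params()]
#'   for experiment 2).
#' @param n_subjects Number of synthetic subjects.
#' @param seed Optional integer seed for full reproducibility.
#' @param no_response_rate,premature_rate Proportions of trials flagged as
#'   missed / premature.  Defaults: 0.004 and 0.002 for experiment 1,
#'   0.009 and 0 for experiment 2.
#' @return A tibble, one row per subject x trial.  Experiment 1 columns
#'   include `rate_hz`, `noise_level`, `ipi_sequence`
#'   (semicolon-joined ms), `response` (slow/fast/none), `rt_ms`,
#'   `pulses_presented`; experiment 2 columns include `gap_ms`, `dp_first`,
#'   `response` (first/second/none) and `correct`.
#' @export
simulate_dataset <- function(schedule, params, n_subjects, seed = NULL,
                             no_response_rate = NULL, premature_rate = NULL) {
  stopifnot(inherits(schedule, "experiment_schedule"))
  experiment <- attr(schedule, "experiment")
  if (experiment == 1L && !inherits(params, "rate_observer_params")) {
    stop("experiment 1 schedule requires `rate_observer_params`", call. = FALSE)
  }
  if (experiment == 2L && !inherits(params, "gap_observer_params")) {
    stop("experiment 2 schedule requires `gap_observer_params`", call. = FALSE)
  }
  if (is.null(no_response_rate)) {
    no_response_rate <- if (experiment == 1L) 0.004 else 0.009
  }
  if (is.null(premature_rate)) {
    premature_rate <- if (experiment == 1L) 0.002 else 0
  }
  maybe_with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      tab <- if (experiment == 1L) {
        subj <- params
        subj$sigma_sense_ms <- params$sigma_sense_ms *
          subject_multipliers(1L, params$subject_cv)
        simulate_subject_exp1(schedule, subj, no_response_rate,
                              premature_rate)
      } else {
        subj <- params
        subj$tau_ms <- params$tau_ms *
          subject_multipliers(2L, params$subject_cv)
        simulate_subject_exp2(schedule, subj, no_response_rate)
      }
      dplyr::mutate(tab, subject_id = sprintf("S%02d", s), .before = 1)
    })
  })
}

# plain tibble copy of a schedule, without its schedule attributes
schedule_trials <- function(schedule) {
  out <- tibble::as_tibble(schedule)
  for (a in c("experiment", "timing", "seed")) attr(out, a) <- NULL
  out
}

simulate_subject_exp1 <- function(schedule, params, no_response_rate,
                                  premature_rate) {
  trials <- schedule_trials(schedule)
  n <- nrow(trials)
  n_ipis <- N_PULSES_MAX - 1L
  ipi <- matrix(NA_real_, n, n_ipis)
  for (r in c(4, 6)) {
    for (lev in NOISE_LEVELS) {
      idx <- which(trials$rate_hz == r & trials$noise_level == lev)
      if (!length(idx)) next
      spec <- rate_stimulus_spec(r, lev)
      ipi[idx, ] <- sample_truncated_normal(
        length(idx) * n_ipis, spec$nominal_ipi_ms,
        spec$noise_level * spec$nominal_period_ms, spec$ipi_floor_ms
      )
    }
  }
  response <- character(n)
  for (m in MODALITIES_EXP1) {
    idx <- which(trials$modality == m)
    response[idx] <- rate_responses_from_ipis(ipi[idx, , drop = FALSE],
                                              m, params)
  }
  rt <- response_times_exp1(n)
  second_onset <- PULSE_MS + ipi[, 1]
  premature <- stats::runif(n) < premature_rate
  rt[premature] <- round(stats::runif(sum(premature), 0,
                                      second_onset[premature]))
  none <- stats::runif(n) < no_response_rate
  response[none] <- "none"
  rt[none] <- NA_real_
  ipi_str <- do.call(paste, c(as.data.frame(round(ipi, 3)), sep = ";"))
  dplyr::mutate(trials,
    ipi_sequence = ipi_str,
    response = response,
    rt_ms = rt,
    pulses_presented = N_PULSES_MAX
  )
}

simulate_subject_exp2 <- function(schedule, params, no_response_rate) {
  trials <- schedule_trials(schedule)
  n <- nrow(trials)
  p <- numeric(n)
  for (m in MODALITIES_EXP2) {
    idx <- which(trials$modality == m)
    if (length(idx)) p[idx] <- gap_pc(trials$gap_ms[idx], m, params)
  }
  correct <- stats::runif(n) < p
  response <- ifelse(correct == trials$dp_first, "first", "second")
  rt <- round(stats::rlnorm(n, log(600), 0.4))
  none <- stats::runif(n) < no_response_rate
  response[none] <- "none"
  correct[none] <- NA
  rt[none] <- NA_real_
  dplyr::mutate(trials,
    response = response,
    correct = correct,
    rt_ms = rt
  )
}
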