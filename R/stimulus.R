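# Pulse-train stimulus model for the rate-categorization task.
#
# A trial's stimulus is a train of up to 10 equal-duration (50 ms) pulses
# separated by empty inter-pulse intervals (IPIs).  The nominal IPI is set by
# the pulse rate (4 Hz: period k = 250 ms, IPI 200 ms; 6 Hz: k = 166 ms,
# IPI 116 ms).  On jittered trials each IPI is independently perturbed by
# zero-mean Gaussian noise with sigma = noise_level * k, truncated at the
# lower tail so that no IPI is ever <= 1 ms.

RATE_PERIODS_MS <- c(`4` = 250, `6` = 166)
NOISE_LEVELS <- c(0, 0.05, 0.10, 0.20, 0.40)
PULSE_MS <- 50
N_PULSES_MAX <- 10
IPI_FLOOR_MS <- 1

#' Specify a rate-categorization pulse-train stimulus
#'
#' Bundles the design constants of one stimulus condition: pulse rate,
#' proportional temporal-noise level, nominal period, pulse duration, the
#' maximum train length, and the lower truncation bound on inter-pulse
#' intervals (IPIs).
#'
#' @param rate_hz Pulse rate in Hz; one of 4 (the "slow" category) or 6
#'   ("fast").
#' @param noise_level Proportional jitter level; one of 0, 0.05, 0.10, 0.20,
#'   0.40.  The IPI jitter standard deviation is `noise_level` times the
#'   nominal period (250 ms at 4 Hz, 166 ms at 6 Hz).
#'
#' @return An object of class `rate_stimulus_spec`: a list with fields
#'   `rate_hz`, `noise_level`, `nominal_period_ms`, `nominal_ipi_ms`,
#'   `pulse_ms` (50), `n_pulses_max` (10) and `ipi_floor_ms` (1).
#' @examples
#' rate_stimulus_spec(4, 0.10)
#' @export
rate_stimulus_spec <- function(rate_hz, noise_level) {
  if (length(rate_hz) != 1 || !rate_hz %in% c(4, 6)) {
    stop("`rate_hz` must be 4 or 6", call. = FALSE)
  }
  if (length(noise_level) != 1 ||
      !isTRUE(any(abs(noise_level - NOISE_LEVELS) < 1e-12))) {
    stop("`noise_level` must be one of 0, 0.05, 0.10, 0.20, 0.40",
         call. = FALSE)
  }
  k <- unname(RATE_PERIODS_MS[as.character(rate_hz)])
  structure(
    list(
      rate_hz = rate_hz,
      noise_level = noise_level,
      nominal_period_ms = k,
      nominal_ipi_ms = k - PULSE_MS,
      pulse_ms = PULSE_MS,
      n_pulses_max = N_PULSES_MAX,
      ipi_floor_ms = IPI_FLOOR_MS
    ),
    class = "rate_stimulus_spec"
  )
}

#' @export
print.rate_stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<rate_stimulus_spec> %g Hz, %.0f%% noise (sigma = %.1f ms), nominal IPI %g ms\n",
    x$rate_hz, 100 * x$noise_level,
    noise_sigma(x$rate_hz, x$noise_level), x$nominal_ipi_ms
  ))
  invisible(x)
}

#' Jitter standard deviation for a stimulus condition
#'
#' The temporal-noise SD scales with the nominal period of the rate
#' condition: `sigma = noise_level * k`, with k = 250 ms (4 Hz) or
#' 166 ms (6 Hz).  Scaling by the period makes the jitter proportionally
#' comparable across the two rates (and makes the 4- and 6-Hz IPI sampling
#' distributions unequal in variance at every nonzero level).
#'
#' @inheritParams rate_stimulus_spec
#' @return Jitter SD in ms.
#' @examples
#' noise_sigma(4, 0.40) # 100
#' noise_sigma(6, 0.05) # 8.3
#' @export
noise_sigma <- function(rate_hz, noise_level) {
  spec <- rate_stimulus_spec(rate_hz, noise_level)
  spec$noise_level * spec$nominal_period_ms
}

# Vectorised sampler from N(mean, sd) truncated (by rejection) to > floor.
# Rejection rather than clipping: the target distribution is a renormalised
# truncated normal with no atom at the bound.
sample_truncated_normal <- function(n, mean, sd, floor, max_rounds = 1000L) {
  if (sd == 0) {
    if (mean <= floor) stop("degenerate sampler: mean below floor", call. = FALSE)
    return(rep.int(mean, n))
  }
  x <- mean + stats::rnorm(n, 0, sd)
  bad <- which(x <= floor)
  rounds <- 0L
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("truncated-normal rejection sampler failed to terminate", call. = FALSE)
    }
    x[bad] <- mean + stats::rnorm(length(bad), 0, sd)
    bad <- bad[x[bad] <= floor]
  }
  x
}

#' Sample inter-pulse intervals for a stimulus condition
#'
#' Draws IPIs as nominal IPI + x, x ~ N(0, sigma^2) with
#' sigma = `noise_level * k`, redrawing (rejection sampling) any draw that
#' would give an IPI <= 1 ms.  At noise level 0 the nominal IPI is returned
#' exactly.
#'
#' @param spec A [rate_stimulus_spec()].
#' @param n Number of independent IPIs to draw.
#' @return Numeric vector of `n` IPIs in ms, all > 1 ms.
#' @export
sample_ipi <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "rate_stimulus_spec"))
  n <- as.integer(n)
  if (n < 0L) stop("`n` must be non-negative", call. = FALSE)
  sigma <- spec$noise_level * spec$nominal_period_ms
  sample_truncated_normal(n, spec$nominal_ipi_ms, sigma, spec$ipi_floor_ms)
}

#' Generate a jittered pulse train
#'
#' Builds one stimulus realization: `n_pulses` pulses of 50 ms, with the
#' `n_pulses - 1` IPIs sampled independently via [sample_ipi()].  Onsets are
#' in ms from the first pulse onset (= 0); each IPI is the empty interval
#' from one pulse's offset to the next pulse's onset.
#'
#' @inheritParams sample_ipi
#' @param n_pulses Number of pulses, between 1 and 10.
#' @return An object of class `pulse_sequence`: a list with
#'   `pulse_onsets_ms`, `pulse_ms`, `ipis_ms` and `spec`.
#' @examples
#' withr::with_seed(1, generate_rate_sequence(rate_stimulus_spec(6, 0.4)))
#' @export
generate_rate_sequence <- function(spec, n_pulses = spec$n_pulses_max) {
  stopifnot(inherits(spec, "rate_stimulus_spec"))
  if (length(n_pulses) != 1 || n_pulses < 1 || n_pulses > spec$n_pulses_max) {
    stop("`n_pulses` must be between 1 and ", spec$n_pulses_max, call. = FALSE)
  }
  n_pulses <- as.integer(n_pulses)
  ipis <- sample_ipi(spec, n_pulses - 1L)
  onsets <- c(0, cumsum(spec$pulse_ms + ipis))
  structure(
    list(
      pulse_onsets_ms = onsets,
      pulse_ms = spec$pulse_ms,
      ipis_ms = ipis,
      spec = spec
    ),
    class = "pulse_sequence"
  )
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf(
    "<pulse_sequence> %d pulses x %g ms, duration %.1f ms (%g Hz, %.0f%% noise)\n",
    length(x$pulse_onsets_ms), x$pulse_ms, sequence_duration(x),
    x$spec$rate_hz, 100 * x$spec$noise_level
  ))
  invisible(x)
}

#' Total duration of a pulse train
#'
#' First pulse onset to last pulse offset, in ms.  A full isochronous
#' 10-pulse 6-Hz train spans 9 x 116 + 50 = 1544 ms; a full 4-Hz train
#' spans 9 x 200 + 50 = 2300 ms.
#'
#' @param seq A `pulse_sequence`.
#' @return Duration in ms.
#' @export
sequence_duration <- function(seq) {
  stopifnot(inherits(seq, "pulse_sequence"))
  if (length(seq$pulse_onsets_ms) == 0) {
    stop("empty pulse sequence has no duration", call. = FALSE)
  }
  max(seq$pulse_onsets_ms) + seq$pulse_ms - min(seq$pulse_onsets_ms)
}
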