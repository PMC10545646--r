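---
title: "Models and methods: visuo-tactile rate categorization and gap detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: visuo-tactile rate categorization and gap detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtacuity)
```

# The scientific problem

How well do the eyes and the skin transmit *temporal* information? Two
classic psychophysical paradigms probe this:

1. **Rate categorization.** A train of up to ten 50-ms pulses is presented
   either visually (LED flashes, `V`) or vibrotactually (`T`), at a nominal
   rate of 4 Hz ("slow") or 6 Hz ("fast"). On most trials the inter-pulse
   intervals (IPIs) are jittered, and the observer must still categorize the
   average rate. Performance is summarised per subject and condition with
   nonparametric sensitivity *A* and decision criterion *b*.

2. **2IFC gap detection.** Two stimuli are shown per trial: a "double pulse"
   containing an unfilled gap of 2–32 ms, and a single continuous pulse of
   matched total duration. The observer reports which interval contained
   the double pulse. A psychometric function links gap duration to accuracy,
   and its inverse at 76% correct (*d′* = 1) defines the gap-detection
   threshold — for visual, tactile, and bimodal (`VT`) stimuli.

The package implements both stimulus models, a synthetic observer that
replaces human subjects so the full analysis chain is testable offline, and
the complete analysis path from raw trial tables to group statistics.

# Stimulus model

The nominal period is *k* = 250 ms at 4 Hz and *k* = 166 ms at 6 Hz (the
printed design constant, deliberately not 1000/6 ≈ 166.7), so nominal IPIs
are 200 and 116 ms after subtracting the 50-ms pulse. Temporal noise is
additive and Gaussian on each IPI, with

σ = noise_level × *k*,  noise_level ∈ {0, 0.05, 0.10, 0.20, 0.40}.

Scaling σ by the period makes the two rates' IPI sampling distributions
unequal in variance at every nonzero level — the reason the analysis uses
*distribution-free* sensitivity estimators rather than the equal-variance
Gaussian *d′*.

Two numerical choices deserve note:

* **Truncation by rejection, not clipping.** The IPI distributions are
  truncated so no IPI is ever ≤ 1 ms. Sampling is by redrawing offending
  values: the result is a properly renormalised truncated normal with no
  probability atom at the bound, which clipping would create.
* **Durations.** A full isochronous 6-Hz train spans 9 × 116 + 50 =
  1544 ms. The corresponding 4-Hz arithmetic gives 9 × 200 + 50 = 2300 ms;
  `sequence_duration()` reports exactly that. (Observed mean durations in a
  live experiment are shorter because subjects may respond before the train
  ends; the package models the full train and reports a `pulses_observed`
  count instead of simulating early stopping.)

Schedules are exactly balanced: experiment 1 has 16 alternating-modality
blocks of 50 trials with every rate × noise cell appearing 5 times per
block (hence exactly 20% isochronous trials and 40 trials per
modality × rate × noise cell); experiment 2 has 9 blocks of 50 with 3
blocks per modality and 30 trials per modality × gap cell. The design
documents only say the conditions were "randomized"; exact within-block
balance is this package's choice, because it makes the printed design
proportions hold exactly rather than in expectation. All randomness flows
from one caller-supplied seed (`withr::with_seed`), so schedules, datasets
and analyses are reproducible bit-for-bit.

# The synthetic observer

No generative observer is specified by the experimental design; the one
implemented here is the minimal model that produces every qualitative
pattern the analyses are meant to detect.

## Rate task

Each IPI is perceived as

IPI′ᵢ = max(0, IPIᵢ − ρ_m) + εᵢ,  εᵢ ~ N(0, σ²_sense,m),

where ρ_m is a modality-specific *persistence* parameter: the sensory
response to a pulse outlasts the pulse, filling in the start of the empty
interval and shortening its perceived duration. The decision statistic is a
weighted mean of the perceived IPIs with geometrically decaying weights
(`weight_decay^(i-1)`, default 0.6), reflecting the finding that early
intervals matter more; the response is "slow" iff the statistic exceeds a
criterion *c* (default 158 ms). A lapse parameter (default 0.02) mixes in
uniformly random responses.

Defaults (σ_sense: V = 60, T = 35 ms; ρ: V = 25, T = 5 ms) encode two
asymmetries: *more precise tactile interval coding* (higher tactile *A* at
every noise level) and *longer visual persistence*. The latter shifts
perceived visual IPIs down, so both 4- and 6-Hz visual trains tend to seem
fast; with the criterion fixed, 4-Hz visual trials are misjudged more often
than 6-Hz ones, which is exactly what *b* > 1 encodes under the
hit = "slow"|4-Hz scoring. The tactile criterion sits near the perceived
tactile midpoint, so *b*_T ≈ 1.

Because the decision statistic is a weighted mean of ~9 intervals, the
per-trial effective noise is σ_sense/√n_eff with n_eff ≈ 3.9 at the default
decay; the defaults were chosen once, by this calculation plus a small
simulation, so that group-level *A* lies near ceiling at 0% noise and falls
to ≈ 0.86–0.89 at 40% noise, matching the qualitative published pattern.

## Gap task

Each unimodal channel has a Gaussian-CDF psychometric function with guess
rate 0.5:

p_m(x) = 0.5 + (0.5 − lapse) Φ((x − τ_m)/s_m),

with defaults τ_T = 5 ms, τ_V = 15.5 ms (tactile acuity ≈ 3× finer),
s = 4 ms. On bimodal trials the judgment comes from the tactile channel
alone with probability π (`tactile_reliance`, default 0.9) and otherwise
from the visual channel — a *probability mixture*, not optimal
variance-weighted integration. The choice is deliberate: empirically,
bimodal thresholds sit slightly *above* tactile-alone thresholds, an
ordering optimal integration cannot produce but a mixture produces
naturally.

## Between-subject heterogeneity

Real subjects differ; simulated subjects must too, or subject-level
correlations are meaningless. Each simulated subject scales its parameters
by lognormal multipliers with mean 1:

* rate task: one shared multiplier on both σ_sense values
  (`subject_cv` = 0.15);
* gap task: independent multipliers on τ_V and τ_T
  (`subject_cv` = 0.7).

The gap-task heterogeneity is what makes tactile and bimodal accuracy
correlate across subjects (both depend on the subject's τ_T through the
mixture) while visual and bimodal accuracy correlate only weakly — the
tactile-dominance signature. The defaults were calibrated once, by a
simulation study at the design's trial counts, so that this contrast is
reliable at n = 14 subjects; they are ordinary config-exposed parameters,
not hard-coded constants. With `subject_cv = 0` the observer population is
homogeneous, which is the cleanest setting for testing estimator recovery.

What the generator does **not** emulate: early stopping and reaction-time
distributions (timing metadata is carried but synthetic RTs are
decorative), sequential dependencies, learning or fatigue, and any genuine
multisensory interaction beyond the mixture. Passing tests therefore
certify the *analysis machinery* and the qualitative structure of the
simulated data, not any claim about human observers.

# Nonparametric sensitivity and criterion

With H the hit rate ("slow"|4 Hz) and F the false-alarm rate
("slow"|6 Hz), the distribution-free estimators (Zhang & Mueller 2005) are
three-branch closed forms; for F ≤ ½ ≤ H,

A = ¾ + (H − F)/4 − F(1 − H),  b = (5 − 4H)/(1 + 4F),

with companion branches for H < ½ and F > ½. Any correct transcription
must satisfy: A = 0.5 whenever H = F; b = 1 exactly on the equal-error
diagonal H = 1 − F; continuity across branch boundaries; and the
error-direction law (b > 1 iff misses outnumber false alarms, strictly
above chance). The test suite asserts all four on dense grids — these
identities, not the formulas, are the contract.

Handling choices the estimators leave open:

* **Boundary rates.** A rate of 0 or 1 in a 40-trial cell is replaced by
  1/(2N) or 1 − 1/(2N). The formulas tolerate boundary values, but the
  correction stabilises *b* near ceiling and is applied uniformly.
* **Below-chance cells** (H < F) are handled by reflection,
  A(H,F) = 1 − A(F,H), and inversion, b(H,F) = 1/b(F,H). On the H = F
  diagonal itself b = 1 even when one error type is more frequent — an
  edge case of the error-direction law worth knowing about, though real
  cells rarely land there.
* **Exclusions.** Rate-task trials are dropped if no response was given or
  the response preceded the second pulse's onset (no rate information yet);
  gap-task trials are dropped only for missing responses, because a short
  RT in 2IFC can be a legitimate first-interval identification.

Estimates are computed per subject × modality × noise cell (10 cells per
subject) and only then averaged, matching the subject-level analysis
convention.

# Psychometric fitting and thresholds

The 2AFC model is a two-parameter logistic with guess rate fixed at 0.5 and
no lapse term:

p(x) = 0.5 + 0.5 · logistic(β₀ + β₁x).

* **Predictor scale.** Gap duration enters in ms on a linear scale; the gap
  set is geometric, but the model statement gives no transform, so none is
  imposed.
* **Optimisation.** BFGS on the binomial negative log-likelihood with
  analytic gradient, relative tolerance 1e-10, and two deterministic
  starts: the fixed (β₀, β₁) = (0, 0.1) and an empirical-logit start
  computed from the observed proportions. The second start exists because
  the 2AFC likelihood is not concave: from a poor start the optimizer can
  settle on the plateau where the fitted curve hugs the 0.5 guess rate.
  The better likelihood wins; fits remain deterministic functions of the
  data.
* **Separation.** All-correct data (or runaway coefficients, |β₀| > 30,
  |β₁| > 15 on these ms scales) flag the fit as non-converged; flagged fits
  yield no threshold rather than a garbage one.
* **Threshold.** x* = (logit(2·0.76 − 1) − β₀)/β₁, so p(x*) = 0.76
  exactly; 0.76 is Φ(1/√2), the unbiased 2IFC percent correct at *d′* = 1.
* **Group fits pool trials** across subjects within modality (the
  alternative, averaging subject proportions, weights subjects equally but
  discards trial counts; pooling was chosen and subject-level fits are
  reported alongside). Subject-level fits are independent per-subject ML
  fits — deliberately simpler than a random-slopes mixed model, and
  sufficient for the correlation and slope analyses that consume them.
* **Bootstrap.** SEs come from resampling trials with replacement within
  each gap cell (equivalent to redrawing each cell count from
  Binomial(n, k/n)), refitting, and re-inverting; default B = 5000.
  Non-converged refits are dropped and counted, with a warning above 20%.
  A subject-level cluster bootstrap is available via `cluster = "subject"`.

A known bias, measured here and worth stating: fitting a *logistic* to
data generated by a *Gaussian-CDF* channel at the five geometric gap
levels overestimates the 76% point by ~3% (tactile), ~6% (visual) and
~11% (bimodal mixture, whose two-channel shoulder is the least
logistic-shaped). The recovery tests therefore check thresholds to a 15%
band around the generating curve's own 76% crossing.

# Secondary inference

* `test_bias_neutral()`: one-sample *t*-tests of b = 1 per condition, with
  Bonferroni correction over the 10 conditions applied to both p-values
  and confidence levels.
* `simple_effect_modality()`: paired *t*-tests of T − V per noise level,
  reported unadjusted (labelled as such in the output).
* `within_subject_se()`: Cousineau subject-centering with Morey's
  √(C/(C−1)) correction — the method is not dictated by the analysis
  description, and Cousineau–Morey is the field standard.
* `unimodal_bimodal_relation()`: Pearson R² with its test, plus the OLS
  slope of bimodal on unimodal accuracy tested against 1 (the complete
  cue-dominance value). Degenerate inputs (exact fits, zero variance) are
  flagged rather than silently propagated.

The omnibus two-way repeated-measures ANOVAs are deliberately not
re-implemented; they are routine statistics available from standard
packages and are outside this package's contribution.

# Problem sizes and determinism

The shipped tests run the full designs at their natural sizes — 28
synthetic subjects × 800 trials for the rate task, 14 × 450 for the gap
task — and 100 replicate experiments for threshold recovery; the complete
suite finishes in well under a minute of simulation time. Every stochastic
stage takes an explicit seed, and `run_pipeline()` derives all stage seeds
from one configured seed, embedding it and a configuration hash in the
result bundle.

# Known limitations

* The observer is a measurement model for the analysis chain, not a theory
  of timing; its persistence and weighting parameters are stand-ins with
  plausible magnitudes, and the geometric early-interval weighting is a
  convenience form.
* The logistic/Gaussian mismatch described above caps threshold-recovery
  accuracy at the few-percent level for unimodal channels and ~10% for the
  bimodal mixture.
* Premature and missed responses are injected at configurable constant
  rates, independent of condition; real lapses are unlikely to be so
  well behaved.
* The external-data adapter validates structure, not semantics: it cannot
  know whether a deposited column really is a reaction time in ms.
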