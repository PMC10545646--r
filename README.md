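# vtacuity

Simulation and analysis tools for visuo-tactile **temporal psychophysics**:
how precisely do the eyes and the skin transmit information carried by the
*timing* of brief pulses?

The package implements two complementary paradigms end to end:

* **Rate categorization.** Trains of up to ten 50-ms pulses at a nominal
  4 Hz ("slow") or 6 Hz ("fast"), presented visually (V) or vibrotactually
  (T). Inter-pulse intervals are jittered with Gaussian noise of SD
  σ = noise_level × *k* (with *k* the nominal period: 250 ms at 4 Hz,
  166 ms at 6 Hz; noise_level ∈ {0, .05, .10, .20, .40}), truncated so no
  interval is ≤ 1 ms. Performance is scored with the nonparametric
  signal-detection indices *A* (sensitivity, 0.5 = chance) and *b*
  (criterion, 1 = neutral; under the hit = "slow"|4 Hz scoring, *b* > 1
  means mistaken "fast" responses outnumbered mistaken "slow" ones),
  using the distribution-free three-branch estimators — e.g., for
  F ≤ ½ ≤ H,

  A = ¾ + (H − F)/4 − F(1 − H),  b = (5 − 4H)/(1 + 4F).

* **2IFC gap detection.** A double pulse containing an unfilled gap
  X ∈ {2, 4, 8, 16, 32} ms versus a single pulse of matched total duration
  (100 + X ms), in V, T, or bimodal (VT) presentation. Accuracy is
  modelled by a guess-rate-0.5 logistic psychometric function
  p(x) = 0.5 + 0.5·logistic(β₀ + β₁x), fitted by maximum likelihood; the
  **gap-detection threshold** is the fitted curve's inverse at p = 0.76,
  the unbiased 2IFC percent correct at d′ = 1, with standard errors from a
  within-cell bootstrap (B = 5000).

Because human data are not required, a configurable **synthetic observer**
generates trial-level responses with the documented structure: tactile
interval coding more precise than visual, longer visual persistence (which
biases visual rate judgments toward "fast"), tactile gap thresholds about
3× finer than visual, and bimodal judgments dominated by the tactile
channel. See `vignette("methods", package = "vtacuity")` for the models,
parameter meanings, and design decisions.

## Worked example

Simulate a full 14-subject gap-detection experiment and estimate
thresholds:

```r
library(vtacuity)

sched  <- build_exp2_schedule(seed = 7)                       # 450 trials
trials <- simulate_dataset(sched, gap_observer_params(),
                           n_subjects = 14, seed = 8)
thr    <- fit_gap_thresholds(trials, B = 1000, seed = 9)
thr[, c("modality", "beta0", "beta1", "threshold_ms", "se_ms")]
#>   modality  beta0 beta1 threshold_ms se_ms
#> 1        T -0.863 0.186         5.08 0.504
#> 2        V -2.182 0.130        17.40 0.913
#> 3       VT -0.682 0.153         4.98 0.622
```

The tactile threshold (≈ 5 ms) is roughly 3× finer than the visual one
(≈ 17 ms): a 5-ms gap between two tactile pulses is detected above 75%
correct while the same visual gap is at chance. The bimodal threshold sits
near the tactile one because simulated bimodal judgments ride mostly on
the tactile channel.

The rate task, with the criterion-vs-neutral tests at 0% noise:

```r
est  <- estimate_sdt(simulate_dataset(build_exp1_schedule(seed = 7),
                                      rate_observer_params(), 28, seed = 8))
bias <- test_bias_neutral(est)          # Bonferroni over the 10 conditions
bias[bias$noise_level == 0, ]
#>   modality noise_level mean_b ci_lo ci_hi    p_raw    p_adj  n degenerate
#> 1        T           0   1.08 0.996  1.16 7.36e-03 7.36e-02 28      FALSE
#> 2        V           0   1.85 1.697  2.01 7.83e-16 7.83e-15 28      FALSE
```

The visual criterion is far from neutral (*b* ≈ 1.9: isochronous 4-Hz
visual trains are frequently misjudged as "fast", the persistence
signature), while the tactile criterion stays near 1 after correction.

`run_pipeline(default_config(seed = 1))` chains every stage — schedules,
synthetic data, exclusions, estimation, and inference — into one
reproducible bundle.

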