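# tdhr — time-domain heart-rate estimation from wrist PPG

`tdhr` estimates heart rate from a wrist photoplethysmography (PPG) signal
using only time-domain operations cheap enough for a microcontroller:
recursive second-order filters, order comparisons and integer sums. It is
aimed at people building or studying wearable heart-rate monitors — firmware
engineers prototyping an algorithm before committing it to C, and signal-
processing researchers who want a transparent, fully testable reference of
this algorithm class.

The wrist is a hostile place for PPG: on a 14-bit front end the cardiac
pulse is ~30–50 counts on an ~11,100-count baseline, and wrist motion
produces transients thousands of counts high. The pipeline:

1. **Conditioning** — a 0.5–2.5 Hz band-pass biquad whose output is clamped
   to limiter bounds *inside the recursion*
   (`y_i = clamp(b₀x_i + b₁x_{i−1} + b₂x_{i−2} − a₁y_{i−1} − a₂y_{i−2}, L_L, L_H)`,
   default ±150 counts), followed by a fourth-order band-pass; the internal
   clamp stops motion transients from charging the filter state, giving
   sub-second recovery instead of seconds of ringing.
2. **Peak detection** — a binary, scale-truncated variant of automatic
   multiscale peak detection (AMPD): a 1-bit local-maxima scalogram
   `m′(k, c) = 0 ⇔ x_c > x_{c−k} ∧ x_c > x_{c+k}` for scales `k ≤ λ_max = 17`,
   scale selection `λ = argmin_k γ_k` over the row sums, peaks where the
   column sum `s_c = Σ_{k≤λ} m′(k, c)` is zero, a half-sample midpoint rule
   for flat two-sample crests, and a quality gate that rejects windows whose
   minimising scale hits the truncation bound.
3. **Motion masking** — the differenced 3-axis accelerometer norm
   `d_i = √(Δgx² + Δgy² + Δgz²)/G` thresholded at `H = 0.0025` and
   debounced at 500 ms; inter-beat periods overlapping flagged motion are
   discarded.
4. **Estimation** — `bpm = 60·fs / median(kept periods)` per sliding window
   (`N` = 128–1024 samples, 2 s cadence), valid only with ≥
   `P = ⌊N·BPM_min/(60·fs)⌋` movement-free peaks (21 at `N = 1024`).

## Worked example

```r
library(tdhr)

# 90 s synthetic wrist recording at 72 bpm with a 3 s motion artifact
art <- data.frame(start_s = 30, duration_s = 3, ppg_counts = 3000, accel_g = 0.5)
rec <- synth_recording(synth_config(duration_s = 90, hr = 72, seed = 42,
                                    artifacts = art))
rec
#> PPG recording: 2880 samples at 32 Hz (90.0 s), with 3-axis accelerometer, with ground truth

fit <- tdhr(rec)
fit
#> Time-domain HR fit: 30 windows of 1024 samples (32 s) at 32 Hz, 2 s cadence
#>   valid windows: 30/30 (100.0%)
#>   heart rate: median 71.1 bpm, range 71.1-71.1 bpm
#>   vs ground truth: MAE 0.89 bpm (hold-last), 0.89 bpm (valid-only)

head(fit$estimates[, c("t", "bpm", "valid", "n_peaks", "n_valid_periods", "lambda")], 4)
#>    t      bpm valid n_peaks n_valid_periods lambda
#> 1 32 71.11111  TRUE      33              30     13
#> 2 34 71.11111  TRUE      35              30     13
#> 3 36 71.11111  TRUE      37              32     13
#> 4 38 71.11111  TRUE      36              31     13
```

Each row is one 32 s window ending at `t`: the bpm estimate, its validity,
how many peaks were detected, how many inter-beat periods survived motion
exclusion, and the scalogram scale `λ` the detector selected (≈ half the
beat period in samples). Here every window is valid — the artifact costs a
few periods per window (`n_valid_periods < n_peaks − 1`) but the median is
untouched, and the estimate sits within 1 bpm of the 72 bpm ground truth
(71.11 = 60·32/27, the nearest integer-sample period). `summary(fit)`
tabulates invalidity reasons, `plot(fit)` draws the trace against ground
truth, and `residuals(fit)` gives signed per-window errors.

A thin command-line wrapper with `run`, `simulate` and `evaluate`
subcommands is installed at `inst/cli/tdhr.R`; configuration is plain YAML
(`read_config()`), recordings are columnar CSV (`read_recording()`).

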