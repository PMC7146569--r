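---
title: "Time-domain heart-rate estimation from wrist PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-domain heart-rate estimation from wrist PPG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdhr)
```

## The problem

A reflective PPG sensor on the wrist sees a very weak pulse: on a 14-bit
front end the cardiac component is typically 30–50 counts riding on a
baseline near 11,100 counts, and any wrist movement produces transients that
are orders of magnitude larger than the pulse itself. This package
implements a purely time-domain estimator designed for that regime and for
very small compute budgets: every stage uses second-order recursive filters,
order comparisons and integer sums, so the same algorithm is implementable
on a microcontroller. The pipeline is

1. two-stage band-pass conditioning, the first stage carrying a nonlinear
   output limiter;
2. a memory-reduced binary variant of automatic multiscale peak detection
   (AMPD) with a noise-quality gate;
3. an accelerometer-derived motion mask that discards movement-affected
   inter-beat periods;
4. the heart rate as the inverse of the median surviving inter-beat period,
   emitted every `shift_s` seconds over a sliding window, with explicit
   validity flags.

## Signal conditioning

Both stages are band-pass with a 0.5–2.5 Hz band at `fs = 32` Hz, which
brackets 30–150 bpm fundamentals, removes the DC baseline and drift below
0.5 Hz, and suppresses high-frequency noise. The sources we follow state the
band but not the design family; we use Butterworth prototypes via the
bilinear transform (`signal::butter`) because a maximally flat passband
introduces no ripple-induced amplitude structure that could bias the
order-based peak detector. Stage 1 is a single biquad (order 2), stage 2 a
fourth-order design split into two biquads by conjugate pole/zero pairing.
Numerically each section is normalised to `a0 = 1` and verified stable
(poles strictly inside the unit circle) at construction.

The distinctive element is the **limiter inside stage 1**: each output is
computed as the usual direct-form-I candidate and then clamped to
`[lower, upper]`, and the *clamped* value is what enters the recursion
state. This is not equivalent to clipping the output afterwards: by
preventing the filter state from charging during a large artifact, the
chain recovers in roughly one pulse period instead of several seconds (the
package's acceptance script measures 0 s vs ≈ 1.8 s to re-enter a ±150
count band after a +3000-count baseline jump). Default bounds are ±150
counts, roughly 100–150 % of the conditioned pulse amplitude for wrist
signals of the morphology above; `conditioning_config(auto_calibrate =
TRUE)` instead sets bounds at ±1.25 × a robust amplitude estimate (median
per-second peak-to-trough of the stage-1 output, halved) over a calm
calibration window, for front ends with different gain.

Zero initial state produces a warm-up transient; the first
`ceiling(2 fs / passband_low)` samples (4 s at the defaults) are flagged and
peaks inside them are discarded rather than padding or mirroring the
stream, which would manufacture data the sensor never produced.

## Binary multiscale peak detection

The classic AMPD algorithm builds a local-maxima scalogram over scales
`k = 1..ceiling(N/2) − 1`: cell `(k, c)` records whether sample `c`
exceeds both neighbours at distance `k`. In its original form the non-max
cells hold `r + 1` with `r ~ U(0,1)` and peaks are columns whose standard
deviation over the retained rows is zero. Two modifications make this
practical on small devices, and both are implemented here as the primary
detector (`detect_peaks`), with the original kept as a cross-checking
oracle (`detect_peaks_original_ampd`):

* **1-bit cells** (`compute_binary_lms`): the random fill carries no
  information — a column is a peak iff all retained cells are zero — so
  cells are stored as single bits and the column statistic becomes an
  integer sum `s_c` with peaks at `s_c = 0`. The zero cells of both
  formulations are defined by the identical comparison, so peak sets agree
  exactly whenever both select the same scale; tests assert this
  structurally and on simulated windows.
* **Scale truncation** (`lambda_max`, default 17): only the first 17 rows
  are computed. The minimising scale of the row-sum vector γ tracks half
  the dominant period, so 17 rows suffice for pulse periods up to ~34
  samples (≈ 56 bpm at 32 Hz) and the matrix shrinks from `N/2 − 1` rows to
  17. A window whose minimiser lands **on** the truncation boundary cannot
  be distinguished from one whose true minimiser lies beyond it; such
  windows are declared too noisy (`quality_gate`) and produce no estimate
  rather than a wrong one.

Indexing: the defining formulas are conventionally written with a matrix
column `i` that examines sample `i − 1` (an artifact of 1-based matrix
layout). Internally columns are the samples themselves; the test suite
pins this mapping against a literal transcription of the shifted-index
form.

Ties in the γ minimum are broken toward the smallest scale — the
conservative choice, since retaining fewer rows never removes a zero
column. Cells outside the defined comparison range `[k+1, N−k]` take the
"otherwise" value 1 and are included in the row sums, which is the literal
reading of the summation over all N columns; this adds 2k to row k and
thus biases the minimiser slightly toward small scales for aperiodic
input. A consequence worth knowing: unstructured noise does **not**
generally trip the gate (its minimiser sits at small k); the gate fires on
windows whose dominant periodicity is too slow for the truncated scale
range, which is exactly the "no usable pulse" condition it exists for.

**Flat peaks.** Weak, coarsely quantised crests can appear as two equal
consecutive samples, invisible to strict-inequality comparisons. These
leave the signature `s[c−2] > 1, s[c−1] = 1, s[c] = 1, s[c+1] > 1` (the two
crest samples fail only the scale-1 comparison, against each other), and a
peak is emitted at the half-sample midpoint `c − 0.5`. The rule is
evaluated on the raw `s` sequence, after the `s = 0` extraction; a midpoint
within one sample of an integer peak is the same crest and is collapsed
onto the integer peak. Downstream period arithmetic operates on real-valued
positions throughout.

## Motion masking

The three accelerometer axes are first-differenced and the Euclidean norm
normalised to `[0,1]`: differencing removes gravity and slow orientation
change, responding only to jerk-like motion. The normaliser `G` is defined
only implicitly by the `[0,1]` requirement over the sensor's full range; we
take `G = 2 · full_range · √3` (the largest possible difference norm — a
rail-to-rail jump on all three axes), the tightest constant for which the
bound is guaranteed. The indicator is thresholded at `H = 0.0025` (±2 g
range) and run-length filtered with `Ts = 500` ms.

The run-length rule deserves a note: the available description of the
spike filter can be read either as removing indications *longer* than
`Ts` or as a debounce removing indications *shorter* than `Ts`, and the
accompanying illustration shows a short blip being eliminated. We default
to the debounce (`spike_rule = "remove_short"`) — discarding long
movement indications would defeat artifact rejection precisely when it
matters — and expose the other reading behind
`motion_params(spike_rule = "remove_long")`.

An inter-beat period is discarded when any sample in
`[ceiling(p_j), floor(p_{j+1})]` is flagged; half-sample peak positions
round inward. Peaks themselves count as "movement-free" (toward the
minimum-peak requirement) when the flag at their rounded position is 0.
Short quiet gaps between flagged runs are not bridged.

## Heart-rate estimate and validity

Within each `N`-sample window the estimate is
`bpm = 60 fs / median(kept periods)`, the median of an even count being the
mean of the two central order statistics (the standard convention; the
sources are silent). The window is valid only if

* the quality gate passed,
* at least `P = floor(N · bpm_min / (60 fs))` movement-free peaks remain
  (`P = 21` at the defaults `N = 1024`, `bpm_min = 40`; whether peaks are
  counted before or after motion exclusion is configurable, after being
  the default — a period pool cannot be supported by peaks that motion
  disqualified),
* at least one period survives exclusion, and
* the rate lies in `[bpm_min, min(220, 60 fs/2)]` — the 220 bpm ceiling is
  ours, a guard against doubled-peak pathologies; the other bound is the
  two-sample floor on a period.

Invalid windows carry a reason code (`gate`, `sparse`, `motion`,
`implausible`) in the output of `sliding_hr()`, and two output conventions
are provided: carrying the last valid value forward (`hold_last_valid`,
the mode a watch display would use) or emitting only valid values together
with the valid fraction.

## Evaluation

`hr_mae()` scores a trace against a reference series (conventionally on a
2 s grid, as ECG-derived ground truth is usually distributed) by nearest
timestamp within ±1 s, in both modes above. The error metric is the mean
*absolute* error in bpm — the defining formula is sometimes printed
without the absolute-value bars, but a signed mean would cancel
symmetric errors and contradict both the metric's name and its use in the
comparative literature. Estimates are timestamped at the window's trailing
edge; with windows up to 32 s scored against 8 s reference windows this
mixes averaging horizons slightly, which is inherent to comparing
variable-`N` configurations on a fixed reference grid.

## The synthetic generator

`synth_recording()` emulates the signal classes the pipeline must handle,
with known ground truth: beat times integrate a constant or time-varying
rate trajectory (Gaussian beat-to-beat jitter, default 2 % of the period,
avoids pathological exact periodicity); each beat contributes an
asymmetric log-normal-shaped pulse (rise ≈ 0.15 s, decay ≈ 0.35 s at a 1 s
period, scaled with the period) of 40 counts on an 11,100-count baseline;
random-walk drift and white noise are added, and the sum is rounded and
clipped to 14 bits. The accelerometer rests at (0, 0, 1) g with 1 mg noise.
Artifact bursts add a 5 Hz oscillation with a tapered-cosine envelope
simultaneously to the PPG (thousands of counts) and the accelerometer
(a configurable fraction of g), emulating a wrist shake.

What it does **not** emulate: real pulse morphology variation (dicrotic
waves, respiratory amplitude modulation), sensor-coupling changes that
alter the baseline without accelerometer signature, and optical artifacts
uncorrelated with motion. Passing tests on this generator therefore
demonstrate the mechanics of the pipeline — filter behaviour, detector
equivalences, masking and estimation arithmetic — not field accuracy on
real wrist data; published evaluations of this algorithm class on real
recordings report mean absolute errors around 10 bpm, dominated by
exactly the unmodelled effects.

## Known limitations

* **Measurable range at 32 Hz.** The γ-minimising scale sits near half the
  beat period, so with `lambda_max = 17` the gate rejects clean signals
  slower than ≈ 58 bpm; and above ≈ 150 bpm the fundamental leaves the
  2.5 Hz passband, leaving a near-sinusoidal residue whose scale choice
  becomes ambiguous (the 3T/2 scale approximates phase opposition better
  than T/2 when T/2 is far from an integer). The practical sweet spot is
  roughly 60–150 bpm, consistent with the band the conditioning chain was
  designed around; both ends announce themselves through the `gate`
  reason code rather than silently wrong estimates.
* **Period quantisation.** Integer-sample peak positions quantise periods
  to 1 sample (0.5 with flat peaks); at 32 Hz a half-sample median offset
  is ≈ `bpm²/3840` bpm — negligible at 60 bpm, 3–7 bpm above 140 bpm.
  This is the price of the pure time-domain design.
* **Motion mask edges.** Burst onsets/offsets below the `H` threshold
  leave a fraction of a second unmasked at each end of an artifact; the
  period-overlap test usually absorbs this because any period touching
  the masked core is discarded whole.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on generated
data at desk scale: windows of 128–1024 samples, recordings of 20–120 s,
100-window simulation studies for the detector-equivalence and gate
checks, and 20 recordings of 60 s for the rate-recovery study. These sizes
give stable statistics for every assertion while keeping the whole suite
in the seconds-to-minutes range.
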