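---
title: "Hybrid motion-artifact detection and correction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid motion-artifact detection and correction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fnirsart)
```

## The signal model and artifact taxonomy

fNIRS hemodynamic recordings are uniformly sampled concentration-change
series (Δ[HbO₂], Δ[Hb], µmol/L) whose physiological content of interest
lies in a narrow low-frequency band, taken here as 0.003–0.04 Hz.
Superimposed on it are cardiac (~1 Hz) and respiratory (~0.3 Hz)
components and, in mobile or long-duration recordings, motion artifacts of
three kinds: *severe oscillations* (large, fast excursions from rapid head
movement), *slight oscillations* (smaller sustained oscillations), and
*baseline shifts* (a lasting level change once the head settles in a new
position, usually co-occurring with an oscillation).

The package's premise is that these classes need different corrections,
so artifacts are classified before they are corrected. Every stage of the
detector is positively homogeneous and translation-invariant, so detection
results do not depend on the gain or offset of the channel — a property
the test suite checks explicitly.

## Detection

The per-sample moving SD `t(n)` uses a centred window of `W = 2k + 1`
samples with `k = round(3 fs)` (~6 s at 10 Hz), in population form
(division by `W`). Only interior samples have a full window; the first and
last `k` samples replicate the nearest interior value, which avoids
spurious boundary detections. Series shorter than `W` are refused with an
error rather than silently shrinking the window.

The dynamic threshold `A(n)` is anchored on order statistics of the sorted
moving SD: `T1`, `T2`, `T3` at 1-based indices `max(1, floor(0.3 N))`,
`floor(0.5 N)`, `floor(0.7 N)` — the "maximum of the first q%" reading,
with ties resolved by sort stability (immaterial for a maximum). The
series is clipped into `[T1, T3]`, filtered at 0.02 Hz with a zero-phase
order-3 Butterworth filter, floored at `T2`, and offset by `3 (T3 − T1)`.

Two readings of the 0.02 Hz filter are defensible: a literal *high-pass*
removes the very baseline the `T2` floor then restores, leaving `A` driven
by slow fluctuations of the moving SD around its clipped midrange; a
*low-pass* would instead track the slow envelope. The package defaults to
the high-pass reading (`thresholdFilter = "highpass"`) and exposes the
alternative as a configuration switch; with either choice the subsequent
floor at `T2` and the `3 (T3 − T1)` offset dominate the threshold's level.

Classification compares `t` to `A` with both boundaries inclusive on the
lower class: `t ≤ A` none, `A < t ≤ 2A` slight, `t > 2A` suspected severe.
Suspected severe runs are decomposed at their troughs into single-peak
segments (flat valleys resolve to their first sample); a segment is
confirmed severe iff its range is at least `6×` the SD of the *whole*
suspected region (sample SD). Oscillation runs separated by less than 1 s
of unlabelled samples are merged before confirmation and baseline-shift
analysis, since slope segmentation and the BS rule presuppose coherent
events.

A baseline shift is declared over an oscillation run iff both adjacent
quiet runs last at least `quietSeconds` (default 5 s; a 4 s flank at 10 Hz
is *not* eligible) and the means of the full flanks differ by more than
half the run's range. The record edges bound the first and last flanks.

The accelerometer strategy substitutes the integrated acceleration
`acc = sqrt((ax² + ay² + az²)/3)` and threshold `B = 2·clip(d; [T/2, T])`
(with `T` the 30% order statistic of acc's moving SD) into the same
classification rule; severe confirmation and BS detection always run on
the fNIRS trace. Whether the accelerometer strategy should also apply the
6×SD confirmation is not prescribed; it is applied in both strategies for
symmetry.

## Correction

**Severe oscillations.** A cubic smoothing spline in Reinsch form
minimises `p Σ w(n)|x(n) − f(n)|² + (1 − p) ∫ |f″|²` with unit weights and
natural end conditions; the banded system `(R + μ QᵀQ) γ = Qᵀ y`,
`μ = (1−p)/p`, is solved sparsely. The abscissa is the *sample index*
(unit spacing), matching the summation grid of the criterion; with the
default `p = 0.99` the fit is near-interpolating, so subtracting it
flattens the excursion while leaving everything outside the segment
bit-identical. Segments shorter than 4 samples are de-meaned instead.
`p = 1` interpolates exactly and `p = 0` reduces to the least-squares
line; both limits are handled explicitly and tested.

**Baseline shifts.** The same spline with `p = 1/fs³` (0.001 at 10 Hz;
smoothing scale `≈ ((1−p)/p)^{1/4} ≈ 5.6` samples) tracks the level change
through the segment; it is subtracted and the fitted value at the
segment's first sample is added back, so the segment rejoins the record at
its pre-shift level. The offset this leaves *after* the segment is
deliberately not patched sample-by-sample: it is left to the final
high-pass, which removes its sustained part. The severe-stage spline is
subtracted without such a DC re-anchor; any small offset it induces is
likewise absorbed by the final high-pass.

**Dual-threshold wavelet denoising.** Detail coefficients of an
artifact-free record are modelled as zero-mean Gaussian; artifacts produce
heavy-tailed outliers. The SD estimate σ̂ is the absolute value of the
sorted coefficient at 1-based index `round(0.1587 L)` (clamped to
`[1, L]`), over *all* detail levels concatenated — the 15.87th percentile
of N(0, σ²) is −σ, so the estimate ignores the artifact-laden upper tail.
The tail probability α maps to the deviate `u` through the two-sided tail
definition `P(|Z| > u) = α`, i.e. `u = qnorm(1 − α/2)`; the printed form
α = 2[1 − Φ(−u)] exceeds 1 for positive `u` and is read as the standard
two-sided tail. Thresholds are `w₂ = u σ̂` and `w₁ = 1.3 w₂`. Zeroing
scans each level in temporal order: a coefficient above `w₁` triggers
removal of the whole contiguous run of neighbours above `w₂`; isolated
coefficients in `(w₂, w₁]` are kept. Neighbour expansion stays within a
level — cross-level adjacency has no temporal meaning. Results are
averaged over `K = 16` unit-sample circular shifts (cycle spinning), which
suppresses the pseudo-Gibbs ringing of a single shift-variant DWT.

**Decomposition depth.** The DWT is a periodized orthogonal pyramid
(Daubechies db3–5, Symlets sym3–5, Coiflets coif3–5; filter banks embedded
as the standard published constants). The depth `M` is the deepest level
whose approximation band `[0, fs/2^(M+1)]` still contains `bandTopHz`
(default 0.04 Hz; `M = 6` at 10 Hz), capped by signal and filter length.
This choice is load-bearing: with a *global* σ̂, decomposing to the
maximum depth permitted by the length would place the hemodynamic band
itself in coarse detail levels whose coefficients dwarf the
fine-level-dominated σ̂, and the threshold rule would zero the signal band
wholesale. Keeping the band of interest inside the never-modified
approximation makes the global estimate coherent: the thresholded details
carry only supra-band content, exactly where oscillation artifacts live.
An explicit `waveletLevel` override is available. The discrete Meyer
(dmey) wavelet is not offered: its conventional 62-tap FIR truncation is
only approximately orthogonal, which breaks the exact-reconstruction
contract the denoiser is built on; the biorthogonal `bior`/`rbio` banks
are likewise out of scope.

**Boundary handling.** Signals whose length is not a multiple of `2^M`
are extended with a linear bridge from the last sample back to the first,
keeping the circular seam continuous in value; the extension is discarded
after reconstruction, so an unmodified round trip reproduces the input to
machine precision (tested against an explicitly assembled orthonormal
matrix as an independent oracle, and to better than 1e-8 through the full
cycle-spinning path).

**Final high-pass.** A zero-phase (forward–backward) order-3 Butterworth
high-pass at 0.003 Hz keeps the band of interest and discards the
sustained part of residual offsets. Two numerical choices matter at so low
a cutoff: the series is mean-centred before filtering (a high-pass rejects
DC, so this is exact, and it removes the start-up transient a constant
offset would excite), and the series is padded by *even* (symmetric)
reflection rather than odd reflection — odd reflection extrapolates the
local trend, which a 0.003 Hz filter turns into a long spurious transient
on 600-s records.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | 0.05 | probability | two-sided tail mass behind `w₂`; performance is flat over 0.005–0.1 (tested) |
| `motherWavelet` | `db4` | — | any of `availableWavelets()`; mean performance varies little across them (tested) |
| `K` | 16 | shifts | cycle-spinning averages; unit-sample circular shifts |
| `pSevere` | 0.99 | — | severe-stage spline smoothing parameter |
| `hpFinalHz` | 0.003 | Hz | final high-pass cutoff = lower band edge |
| `hpThresholdHz` | 0.02 | Hz | filter on the clipped moving-SD series |
| `quietSeconds` | 5 | s | minimum BS quiet-flank duration |
| `bandTopHz` | 0.04 | Hz | upper band edge driving the DWT depth |

## The synthetic benchmark

No public dataset accompanies the method, so evaluation uses synthetic
records built to the same taxonomy. `generateClean()` shapes white
Gaussian noise to the 0.003–0.04 Hz band in the frequency domain (unit SD,
zero mean) and adds small cardiac (1.1 Hz, amplitude 0.05 SD) and
respiratory (0.3 Hz, 0.08 SD) sinusoids. `injectArtifacts()` adds, with
ground truth and ≥ 30 s spacing: spikes (Gaussian-windowed 1–3 Hz bursts,
10 SD, 2 s — severe), slow oscillations (Hann-windowed 0.1–0.3 Hz
excursions, 3 SD, 30 s — slight; the carrier sits above the hemodynamic
band, where an in-band denoiser can in principle remove it, and below the
spike band), and baseline shifts (raised-cosine 1-s rise of 3 SD, sustained
to the end of the record, as a settled head position persists). The
default benchmark is 20 independent segments of 600 s at 10 Hz — a
desk-scale problem size chosen so the whole evaluation, including
parameter sweeps, runs in minutes.

What the generator does *not* emulate: real motion noise drawn from
recordings (the artifact families here are parametric shapes), slow
instrumental drift, superficial-layer (scalp) hemodynamics, Mayer waves,
heteroscedastic measurement noise, or channel-to-channel structure.
Passing the benchmark therefore demonstrates that the pipeline corrects
the *taxonomy* it targets under controlled conditions, not that it is
validated on any particular instrument's data.

## Degenerate inputs and numerical conventions

* Intervals are 1-based closed in samples internally (`IRanges`); files
  record half-open seconds, `[(start−1)/fs, end/fs)`.
* A constant signal yields `t ≡ 0`, `A ≡ 0`, and an empty annotation
  (`t ≤ A` everywhere).
* Quantile indices floor with a minimum of 1; the σ̂ index rounds and is
  clamped to `[1, L]`.
* Regions shorter than 3 samples are a single slope segment; severe
  segments shorter than 4 samples are de-meaned rather than spline-fitted.
* SNR with an exactly zero residual returns the documented `+Inf`
  sentinel; report files carry it as the string `"Inf"`, never silently as
  a number.
* Sliding-median recombination (window 600, step 10) evaluates on the
  decimated grid and linearly interpolates back to full length.
* The spline solver is validated against a dense independent solve and an
  objective-minimisation check; the DWT against an explicit orthonormal
  matrix; σ̂ against Monte Carlo at L = 1e5 (within 2%).

## Known limitations

* A baseline shift is corrected *within* its detected segment; the offset
  it leaves afterwards is only attenuated by the 0.003 Hz high-pass, which
  on 600-s records removes it partially (the dominant residual in the
  benchmark). Longer records fare better, since the transient occupies a
  smaller fraction of the record.
* Detection of baseline shifts whose height is comparable to the local
  signal range is inherently marginal under the half-range rule; missed
  shifts pass to the output uncorrected.
* Slight oscillations overlapping the hemodynamic band itself cannot be
  separated by any in-band method and are out of scope for the wavelet
  stage by construction.
* The 6×SD severe confirmation uses the SD over the whole suspected
  region; a region dominated by one huge excursion inflates that SD and
  can demote smaller co-occurring events to slight.
* Single-channel processing only: no co-located-channel regression, ICA,
  or accelerometer-fusion correction.
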