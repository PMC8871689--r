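# fnirsart

Hybrid motion-artifact detection and correction for functional
near-infrared spectroscopy (fNIRS) time series.

## The problem

fNIRS measures cortical hemodynamics (Δ[HbO₂], Δ[Hb], in µmol/L) optically
through the scalp, which makes it portable enough for long-term monitoring —
and correspondingly exposed to head movement. Motion contaminates the
recordings with three distinct artifact classes:

* **severe oscillations** — large, fast fluctuations from rapid head motion;
* **slight oscillations** — smaller sustained oscillations from gentle
  motion;
* **baseline shifts (BS)** — a lasting level change after the head settles
  in a new position.

No single correction technique handles all three: wavelet filters excel at
spikes but leave baseline shifts behind, spline subtraction handles shifts
but not fast spikes. `fnirsart` implements a hybrid approach for users of
long-duration fNIRS recordings (e.g. whole-night sleep monitoring):
detection classifies each artifact first, and each class then receives the
correction suited to it.

## The method

**Detection.** For a signal x(n) sampled at f_s, the two-sided moving SD

t(n) = sd( x(n−k … n+k) ),  k = round(3 f_s), W = 2k + 1

is compared against a *dynamic threshold* A(n) built from the order
statistics T₁, T₂, T₃ of t (at the 30/50/70% sorted positions): t is
clipped into [T₁, T₃], filtered with a zero-phase 0.02 Hz filter, floored
at T₂, and offset by 3(T₃ − T₁). Samples are classified by

* t > 2A — suspected severe oscillation,
* A < t ≤ 2A — slight oscillation,
* t ≤ A — none.

Suspected severe regions are split into single-peak segments at their
troughs; a segment is confirmed severe iff its range reaches 6× the SD of
the whole suspected region. A baseline shift is marked over an oscillation
run when the mean levels of the ≥ 5 s quiet flanks on either side differ by
more than half the run's range. Detection can alternatively be driven by a
3-axis accelerometer: acc(n) = √((a_x² + a_y² + a_z²)/3), with threshold
B(n) = 2·clip(d(n); [T/2, T]) on acc's moving SD d.

**Correction** proceeds in three stages (x → x₁ → x₂ → x₃ → y):

1. *Severe oscillations*: a cubic smoothing spline (penalised criterion
   p Σ|x−f|² + (1−p) ∫|f″|², p = 0.99) is fitted inside each severe
   segment and subtracted.
2. *Baseline shifts*: a heavily smoothed spline (p = 1/f_s³) is subtracted
   inside each BS segment and the fitted value at the segment start is
   added back, re-anchoring the DC level.
3. *Slight oscillations*: dual-threshold wavelet denoising. The detail
   coefficients of a periodized orthogonal DWT are modelled as N(0, σ²);
   σ̂ is the |value| at the sorted position nearest 0.1587·L (the 15.87th
   percentile of a Gaussian is −σ). With u the two-sided normal deviate for
   tail mass α (default 0.05), the *processing* threshold is w₂ = u·σ̂ and
   the *detecting* threshold w₁ = 1.3·w₂. Wherever |w| > w₁, the outlier
   run is expanded over contiguous neighbours with |w| > w₂ and zeroed;
   isolated coefficients between the thresholds are kept. The result is
   averaged over K = 16 circular shifts (cycle spinning) to suppress
   pseudo-Gibbs ringing, and finally high-passed at 0.003 Hz to keep the
   hemodynamic band of interest (0.003–0.04 Hz).

For optical-density inputs, the modified Beer–Lambert law converts
dual-wavelength ΔOD to hemoglobin changes,
Δ[HbO₂] = (a₁ΔOD_λ1 + a₂ΔOD_λ2)/L and Δ[Hb] = (b₁ΔOD_λ1 + b₂ΔOD_λ2)/L,
with packaged 735/850 nm coefficients (330.1717, −131.3958, −127.6967,
184.5598) and a linear-solve constructor for other wavelength pairs.

A synthetic benchmark generator (`generateClean()`, `injectArtifacts()`,
`makeBenchmark()`) produces band-limited clean signals with injected
spikes, slow oscillations and baseline shifts plus ground-truth
annotations, and the evaluation harness scores corrections by SNR and
Pearson R against the clean reference.

## Worked example

```r
library(fnirsart)

ds  <- injectArtifacts(generateClean(600, fs = 10, seed = 11), seed = 12)
res <- correctPipeline(ds@noised)

annotationToDf(usedAnnotation(res))[8:9, ]
#>   start  end       category source
#> 8  1613 1658         slight  fnirs
#> 9  1613 1658 baseline_shift  fnirs

snr(ds@clean, ds@noised)                  # -14.45 dB
snr(ds@clean, correctedSignal(res))       #   4.71 dB
pearsonR(ds@clean, ds@noised)             #   0.358
pearsonR(ds@clean, correctedSignal(res))  #   0.846
```

The detector finds the injected events (the segment shown is a detected
baseline shift riding on an oscillation run at samples 1613–1658, i.e.
161.2–165.8 s); correction lifts this record from −14.45 dB to +4.71 dB
SNR and from R = 0.358 to R = 0.846 against the clean reference. On the
default 20-segment benchmark the hybrid pipeline gains ~9.9 dB in the mean
and beats the single-threshold wavelet and sliding-median comparison
methods on both metrics:

```r
summariseBenchmark(runBenchmark(makeBenchmark(20, 600, 10, seed = 1)))
#>           method  n snr_noised_mean snr_processed_mean ... r_noised_mean r_mean
#> 1  median_filter 20           -6.56              -6.93 ...         0.545  0.130
#> 2       proposed 20           -6.56               3.31 ...         0.545  0.816
#> 3    spline_only 20           -6.56              -6.43 ...         0.545  0.550
#> 4 wavelet_single 20           -6.56              -6.07 ...         0.545  0.574
```

A command-line interface covering `simulate`, `detect`, `correct` and
`evaluate` is installed at `inst/scripts/fnirsart`:

```sh
Rscript inst/scripts/fnirsart simulate --duration 600 --seed 1 --out-prefix run
Rscript inst/scripts/fnirsart correct --input run_noised.csv --fs 10 --out corrected.csv
```

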