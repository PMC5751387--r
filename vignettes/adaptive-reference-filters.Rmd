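---
title: "Adaptive similarity-based spatial referencing: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive similarity-based spatial referencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the model assumptions behind the adaptive reference filters, every tunable
parameter with its default and rationale, the synthetic data the tests rely
on, and the places where the published procedure is underdetermined and the
package had to commit to a reading.

## 1. The filtering model

A multichannel EEG sample is modeled as
`V_i(k) = s_i(k) + c(k) + n_i(k)`: a channel-specific neural component
`s_i`, a *common interference* `c` broadcast across the scalp with the same
phase and similar amplitude (line pickup, EOG, shared rhythms), and
channel noise `n_i`. Reference filters estimate `c` from neighbors and
subtract it. Because the weights sum to one, any waveform that is exactly
identical across channels is cancelled *exactly* — an algebraic identity
the test suite asserts to 1e-10 for the adaptive and baseline filters
alike.

The adaptive filters depart from fixed inverse-distance weights in three
stages per output sample, all computed causally from the trailing
similarity window:

1. **Neighbor selection.** The per-sample amplitude dispersion
   `Vstd = sqrt(sum_j (V_j - V_i)^2 / (N-1))` is tracked against running
   extremes; its adaptive threshold maps dispersion near the running
   minimum to a permissive level near the maximum and vice versa, with the
   running maximum capped at `cap_ratio` times the minimum. Below
   threshold, all neighbors are kept; above it, only neighbors whose
   windowed concordance correlation (CCC) with the target exceeds a
   median-based threshold survive.
2. **Virtual distances.** `VD = exp(-w1 * ccc)`; normalized to weights.
   High concordance means the neighbor records the same information as the
   target, so it is "virtually close" and contributes little — the
   mechanism that preserves target-localized components where classic
   WAR/LAR attenuate them.
3. **Amplitude correction.** If the *selected* set is still dispersive,
   per-electrode medians over correlation-compatible subsets replace a
   robust estimate of the excursion before subtraction.

Assumptions worth stating: the common interference must dominate the
*within-window* covariation between channels for CCC to rank neighbors
usefully; the montage must contain at least one neighbor that carries the
interference but not the target's signal; and the artifact model is
"rare, large, and local" — a burst on many channels at once looks like
common mode and is deliberately not rejected.

## 2. Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `window_ms` (Wf) | 100 | ms | similarity window; shorter reacts faster but makes CCC noisier (25 samples at 250 Hz is near the floor) |
| `w1` | 5 | – | virtual-distance gain; `exp(-w1*ccc)` spans e^10 over the CCC range, so weight concentration grows quickly with w1 |
| `cap_ratio` | 10 | – | cap on `Vstd_max / Vstd_min`; prevents one huge artifact from pinning the threshold permanently |
| `r_cut` | 0.85 | – | Pearson cutoff of the amplitude-correction grouping |
| `ccc_tol` | 0.05 | – | closeness tolerance of the similarity threshold |
| `eps` | 1e-6 | µV | floor on the running dispersion minimum |
| `warmup_policy` | baseline_weights | – | output while the window fills: distance-weighted reference (keeps early output referenced) or passthrough |

The defaults for `Wf`, `w1` and `cap_ratio` are the fitted operating point
reported for this method; `tune_filter_params()` re-runs the sweep
(windows, cap ratios, `w1`) on synthetic records scoring mean SNR minus
mean |attenuation| for users who want to refit.

## 3. What the synthetic generators emulate — and what they do not

`gen_ssvep()` composes: common components (one waveform, per-channel
gains) — line tone, 1/f pink noise, slow drift, raised-cosine EOG blinks of
200–400 ms; channel-local sinusoids with harmonics (the SSVEP, phase-locked
across its carriers); independent Gaussian channel noise; and optional
multiplicative single-electrode bursts. Pseudo-random streams are split
per component from the master seed, so adding a component never perturbs
another's realization. `gen_gait_epochs()` emulates a cued-gait protocol at
400 Hz: 24 planning epochs of 1.5 s carrying a quadratic negative ramp
(6 µV terminal amplitude) and a 50% mu-rhythm desynchronization on
Cz/CP1/CP2, and 36 rest epochs of 2.0 s, over 6 sessions, all sharing an
EOG-like common mode (20 µV), a line tone, and 5 µV channel noise. Those
amplitudes are in the range a clinical EEG reader would call plausible
(MRCP of a few µV under tens of µV of background and EOG).

Not emulated: volume conduction with realistic mixing (gains are scalar),
non-stationary background spectra, electrode impedance drift, muscle
artifact broadband bursts, or inter-subject variability. Passing tests
therefore show the algorithms behave as specified under the stated
statistical structure, not that the decoding accuracies transfer to real
recordings — real-data accuracies depend on effect sizes the generator
fixes by construction.

## 4. Numerical and procedural choices

* **CCC moments** are biased (divide-by-n), matching the printed 1/n sums.
  Degenerate windows: two equal constants give 1, unequal constants give 0
  with a `degenerate` attribute — flat segments must not poison selection.
* **Window alignment**: the window ending at sample k covers
  `[k-n+1, k]`; warm-up is `k < n`.
* **Weight normalization** uses max-subtracted exponentials; the batch and
  streaming paths use the *same* stabilization offset, and the batch
  selective branch recomputes windowed CCC with the same call sequence as
  streaming, because last-bit differences between a cumulative-sum rolling
  estimate and a direct window estimate can flip a strict threshold
  comparison and desynchronize the two paths. Batch equals streaming
  sample-for-sample, and output at time t is provably independent of
  samples after t (both are tested).
* **Similarity threshold (selection stage)**: the deviation term is the
  median *absolute* deviation from the median CCC. A signed median is ~0
  for any near-symmetric set, which would make the selective branch of the
  threshold unreachable. A consequence of the median-based rule is that the
  selected set can never be empty (the median neighbor always passes); the
  single-best-neighbor fallback in the code is defensive only.
* **Amplitude-correction trigger**: the dispersion is *recomputed over the
  selected set* and compared against the threshold *re-evaluated at that
  updated dispersion* (the threshold is a function of the current
  dispersion, so updating one updates the other). Excluding a bursty
  neighbor is then sufficient to leave the remaining amplitudes untouched;
  corrections engage only when the artifact survives selection, e.g. on
  the target itself.
* **Amplitude-correction grouping**: for electrode e, `Se` collects
  members whose windowed Pearson r with e reaches `r_cut`; the correction
  is the median over `Se` when it has at least two members and over the
  full selected set otherwise — a singleton `Se` median would return the
  electrode's own value and null its signal. A singleton selected set gets
  zero correction for the same reason.
* **Running extremes** are session-running by default ("throughout the
  time"); `vstd_min` is floored at `eps` to keep the threshold mapping
  finite, and the degenerate range `M* <= 2*Vstd_min` returns an infinite
  (accept-all) threshold with a flag.
* **Inequalities** are strict exactly where the method's wording is strict:
  all-pass requires dispersion strictly *below* threshold, selection
  requires CCC strictly *above* its threshold, corrections require
  dispersion strictly *above* threshold.
* **Feature bank**: RF is the mean filtered amplitude over the 250 ms
  window (a last-sample option exists); the combined fractal dimension is
  the arithmetic mean of the Sevcik and Higuchi estimates; band powers are
  power (not magnitude) sums over half-open bands `[lo, hi)` so shared
  edges are never double-counted, zero-padded to at most 1 Hz spacing and
  normalized so the total equals the time-domain mean square. The
  0.1–4 Hz band is resolution-limited at 250 ms windows: it captures the
  first few padded bins, not a true 0.1 Hz resolution. Higuchi's `kmax`
  defaults to 8 for 100-sample windows. Note the Sevcik estimate
  approaches 1 on a straight line only as `1 + ln(sqrt 2)/ln(2(N-1))`, so
  line-calibration checks use N = 1000.
* **Representation-entropy threshold**: the descending Z screen against
  the maximum uses the pooled standard deviation *plus a local-gap cut*
  (stop at the first adjacent gap exceeding three times the median gap of
  the retained run). Pooled subset REs are multimodal — one cluster near
  `ln m` per subset size m — and the global-sd screen alone reaches far
  down the distribution, putting the threshold near `ln 2` and preventing
  the redundancy-elimination loop from ever engaging; the gap cut confines
  the retained set to the near-maximum cluster. Ties in the minimal-MICI
  pair break lexicographically; candidate scoring ties break to the first
  candidate in order; the loop stops when the working-set RE exceeds the
  threshold or the set would drop below two features.
* **Classifier stage**: features are standardized by training-fold
  statistics; the linear-margin SVM is an invoked component (`e1071`),
  with the box constraint chosen by 2-fold inner cross-validation on the
  composite `Idx` loss (`FPRmax` = maximum per-class false-positive rate,
  `PNMmin` = minimum per-class prediction quality), ties to the smallest
  C. Outer folds group whole sessions (k2 = 3) so train and test never
  share a session. Because planning and rest epochs differ in length and
  count, window-level classes are imbalanced (~67/33); the pipeline
  subsamples the majority class per fold (seeded) so that chance accuracy
  is 0.5 — the null-calibration check depends on this design choice.
* **Timing rule**: a planning command requires the label to persist
  `round(0.088 * fs)` samples (35 at 400 Hz); latency is the time the
  first qualifying persistence completes, negative values anticipating the
  onset; continuous-recognition minimum/maximum are the median and maximum
  qualifying run lengths.

## 5. Problem sizes used by the tests and the acceptance script

Desk-scale sizes, chosen so the full suite runs in minutes: SSVEP records
of 5 s at 250 Hz on a 13-electrode occipital montage; preservation compared
over 20 seeded records; gait pipelines at the protocol's full 24 + 36
epochs with feature stride 25 samples (62.5 ms; stride 1 reproduces the
per-sample scheme at proportional cost), 20 null seeds and 3–5 effect
seeds; oracle equivalence on 1000 random inputs per formula. The
acceptance script reports means over these runs; all randomness descends
from its `--seed`.

## 6. Known limitations

* A multiplicative burst crosses zero, and samples where the bursty
  channel's instantaneous dispersion slips under the adaptive threshold
  re-enter the reference with a *large* virtual-distance weight (low CCC
  maps to the largest weight). The filter's output during such samples can
  deviate noticeably; the tests therefore assert exclusion rates during
  the burst and cleanliness of the output *outside* the burst-active
  interval, which is what the selection stage can guarantee. Detection
  also lags burst onset by design: the similarity window is causal.
* The selection stage's all-pass share depends on neighbor count: with
  many neighbors (WAR-style) dispersion concentrates and quiet records
  stay near-fully permissive; with 3–4 neighbors (LAR-small) the
  dispersion's heavy lower tail drags the running minimum down and the cap
  then keeps the filter selective on a substantial fraction of samples.
* The RE/MICI loop's stopping threshold sits near the maximum pooled RE,
  so on weakly correlated feature sets it either stops immediately (full
  retention) or prunes deeply; the intermediate selected sizes reported on
  real recordings arise from correlation structure the synthetic features
  only partly reproduce.
* EDF input is not supported in this build; signal I/O is labeled CSV.
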