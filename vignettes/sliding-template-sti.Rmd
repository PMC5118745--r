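---
title: "Sliding-template annotation of systolic time intervals in seismocardiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-template annotation of systolic time intervals in seismocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(scgsti)
```

## The problem

The seismocardiogram (SCG) is the dorso-ventral acceleration of the sternum
produced by the beating heart. Two of its fiducial points carry most of the
clinical information: the aortic-valve opening peak (AO) and the
aortic-valve closure peak (AC), with the mitral-valve opening valley (MO)
just after AC. Together with the ECG Q-peak they define the systolic time
intervals:

* **PEP** (pre-ejection period) = Q → AO,
* **LVET** (left-ventricular ejection time) = AO → AC,
* **QS2** (electro-mechanical systole) = Q → AC = PEP + LVET.

AO is a large, stable peak and is easy to find. AC and MO are small,
drift with heart rate, and sit in a stretch of signal where noise and
motion artifacts routinely produce spurious extrema. Manual annotation is
the usual fallback; this package automates it.

## The algorithm

The pipeline is anchored on the ECG and bootstrapped by ensemble
averaging:

1. **Preprocessing.** Both channels pass through 5th-order Butterworth
   band-pass filters — [1, 35] Hz for the SCG, [1, 100] Hz for the ECG —
   with the same design order on both channels so no relative latency is
   introduced. Default application is zero-phase (forward–backward), which
   removes group delay entirely; see *Numerical choices*.
2. **R-peaks** are detected with the Pan–Tompkins chain (QRS band-pass,
   derivative, squaring, 150 ms moving-window integration, adaptive dual
   thresholds with search-back and a 200 ms refractory period), then
   refined to the local ECG maximum. Any replacement detector can be
   plugged in via `annotator_config(rpeak_detector = ...)`.
3. **Initial template.** The first `n_it = 60` beats are segmented around
   their R-peaks into windows of length `w` (the rounded median RR of
   those beats), with the anchor at sample `floor(s*w) + 1`, `s = 0.2`.
   Their per-sample mean is the initial template. In it, Q is the ECG
   minimum within 80 ms before R; AO is the highest SCG peak 45–120 ms
   after Q (a deliberately relaxed PEP range); AC and MO are the highest
   peak and lowest valley 240–350 ms after AO (a relaxed LVET range).
4. **AO tracking.** PEP varies little beat to beat, so each beat's AO is
   simply the segment maximum within ±`ao_tol_ms` (default 20 ms) of the
   previous beat's AO. AO is tracked over the initialization beats too, so
   the sliding window is fully seeded when diastolic annotation starts.
5. **Sliding template.** Because the R–AO distance varies, segments are
   re-cut aligned on AO (same `w` and `s`, so the template AO position
   `AO_T` is constant). For beat *i* the sliding template is the mean of
   the previous `min(i-1, n_sl)` AO-aligned segments (`n_sl = 15` by
   default). Its AC position is tracked recursively:
   `AC_T(i)` = template maximum over
   `[AC_T(i-1) - tol_ac_sl, MO_T(i-1) - tol_mo_sl]`, and
   `MO_T(i)` = template minimum over `[AC_T(i), MO_T(i-1) + tol_mo_sl]`.
   The asymmetric bounds encode that the mitral valve opens after the
   aortic valve closes, and keep the windows short. The recursion starts
   from the initial template: `AC_T(0) = AO_T + LVET_IT`,
   `MO_T(0) = AC_T(0) + (MO_IT - AC_IT)`.
6. **Refinement.** The template positions are carried back to the actual
   beat: AC is the segment maximum over `[AC_T(i) - tol_ac, MO_T(i)]` and
   MO the minimum over `[AC(i), MO_T(i) + tol_mo]` — the MO window is
   anchored at AC(i) because the mitral valve opens only after the
   aortic valve has closed.
7. **STI.** Q per beat is the template Q–R offset applied to each R;
   PEP, LVET, QS2 follow by arithmetic.

The point of the sliding template is error containment: a spurious peak
in one beat contributes at most `1/n_sl` of the template amplitude, so a
single corrupted beat cannot drag the search windows away for long —
errors decay within `n_sl` beats. With `n_sl = 1` the template degenerates
to the previous beat and error propagation returns.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `n_it` | 60 | beats | initialization block averaged into the initial template |
| `n_sl` | 15 | beats | sliding-template depth ("generalized-15") |
| `s` | 0.2 | — | anchor fraction within each segment |
| `ao_tol_ms` | 20 | ms | AO search half-width around the previous AO |
| `tol_ac_sl_ms`, `tol_mo_sl_ms` | 20 | ms | template-domain tracking tolerances |
| `tol_ac_ms`, `tol_mo_ms` | 20 | ms | refinement tolerances on the raw segment |
| `pep_range_ms` | [45, 120] | ms | AO search range after Q (initial template) |
| `lvet_range_ms` | [240, 350] | ms | AC/MO search range after AO (initial template) |

The tolerances sit in the middle of the broad low-sensitivity region that
the parameter grid search exposes (`grid_search()`); performance is flat
around them, which is exactly why a generalized parameter set is usable
across subjects. `n_sl` trades robustness (larger is cleaner) against
responsiveness to genuine LVET drift and warm-up data; depth 15 performs
indistinguishably from depth 40 at a quarter of the history.

## The synthetic test substrate

The study recordings behind this design are not publicly deposited, so
the package ships a seeded generator (`synthetic_spec()`,
`generate_record()`) that provides exact ground truth. It emulates the
features the annotator must cope with:

* quasi-periodic beats: RR jitter (2% CV) plus respiratory sinus
  arrhythmia (3% at 0.25 Hz);
* an ECG built from Gaussian P/Q/R/S/T lobes, Q 25 ms before R;
* an SCG systolic complex — a Gaussian-windowed 20 Hz cosine (inside the
  [1, 35] Hz band, so filtering barely perturbs it) whose largest
  positive extremum *is* the true AO sample, at Q + PEP;
* a smaller diastolic complex: a positive lobe at the true AC (AO + LVET)
  and a negative lobe at the true MO (AC + 40 ms);
* slow sinusoidal drift of PEP (90 ± 5 ms) and LVET (300 ± 10 ms) at
  0.05 Hz, so the template track is genuinely exercised;
* respiration-like amplitude modulation (10%) of the SCG;
* white Gaussian noise to a configured SNR, applied to each channel
  relative to its own clean power (the ECG also gets noise so R-detection
  is tested realistically);
* optional motion artifacts (`inject_artifact()`, `corrupt_beats()`).

Every fiducial is placed at an integer sample and returned as ground
truth, so accuracy can be scored at the ±1-sample level. Separate RNG
substreams drive RR jitter, amplitude modulation and noise: two seeds
with the same rhythm parameters share their ground truth exactly.

What the generator does **not** emulate: the richer multi-lobe morphology
of real SCG complexes, inter-subject morphology variability, baseline
wander, electrode/sensor artifacts with structure, and arrhythmic beats.
Passing tests on this substrate therefore demonstrate the algorithm's
tracking logic, noise behaviour and error containment — not clinical
performance on human recordings.

## Numerical choices

* **Zero-phase filtering.** The application direction of the published
  filters is not stated; we default to forward–backward application
  (doubling the effective order, squaring the magnitude response) because
  offline annotation gains nothing from causality and zero group delay
  keeps ECG/SCG latencies matched exactly. A causal mode remains
  available (`filter_spec(mode = "causal")`).
* **Second-order sections.** A 5th-order band-pass with a 1 Hz corner at
  fs = 500 Hz is an order-10 recursion whose direct form loses ~3 decimal
  digits; the filters are therefore applied as a cascade of analytically
  derived biquads (identical response, full double precision). Inputs are
  reflect-padded by three low-corner time constants to suppress start-up
  transients.
* **Rounding.** All ms→sample conversions use one rule,
  `round(ms * fs / 1000)` half-away-from-zero, so a 2 ms threshold is
  exactly 1 sample at 500 Hz. `w` is the nearest-integer median RR.
* **Tie-breaks.** Every windowed argmax/argmin resolves ties to the
  leftmost sample; the whole pipeline is bit-deterministic.
* **Indexing.** All sample indices are 1-based (R convention); the anchor
  of a segment is its `floor(s*w) + 1`-th sample.
* **Window clipping.** Search windows that leave a segment are clipped
  and the beat flagged; a window that vanishes after clipping keeps the
  previous template state. One bad beat must not abort a record.
* **Degenerate inputs.** Flat ECG yields an empty R-peak series with a
  warning; a flat template window yields leftmost-edge landmarks with a
  warning; beats whose fiducials violate q ≤ AO < AC < MO are blanked and
  flagged rather than propagated.
* **SNR convention.** Noise injection (`add_noise()`) references the mean
  square of the band-pass-filtered SCG in both the pre- and
  post-filtering stages, so "0 dB" always means equal in-band powers.

## Worked example

```{r example}
gt <- generate_record(synthetic_spec(duration_s = 120, snr_db = 20, seed = 1))
ann <- annotate_record(gt$record)
ann
glance(ann)
```

```{r plots, fig.height = 3}
autoplot(ann)                      # per-beat STI series
autoplot(ann, what = "template")   # initial template with landmarks
```

Scoring against the generator's ground truth:

```{r score}
score_annotation(ann, gt$truth)
```

## Evaluation machinery

* `nmp()` — misclassified peaks: detections farther than ζ (default 2 ms
  = 1 sample) from truth; `detection_accuracy()` is its exact complement.
* `bland_altman()` — bias and 1.96 SD limits of agreement of
  truth − measurement (sample SD, n − 1), with `autoplot()`.
* `add_noise()` — SNR-controlled Gaussian noise, before or after the
  band-pass.
* `grid_search()` — NMP surface over (`n_sl`, `tol_ac_sl_ms`,
  `tol_ac_ms`), ties to the smallest depth and tolerances.
* `compare_configs()` — paired two-sided Wilcoxon signed-rank on
  per-record accuracies.

## Problem sizes used in the test suite

The packaged tests run the full pipeline on 3-minute records (about 180
beats at 60 bpm, 120 of them diastolically annotated after the 60-beat
initialization): one record at 20 dB SNR for end-to-end recovery, 20
seeded records across SNR ∈ {20, 10, 5, 0} dB in both noise stages for
the monotonicity study, and the same 20 records at −3 dB post-filtering
noise for the depth comparison. The depth comparison deliberately uses
noise slightly above in-band signal power: the diastolic lobe is the only
structure inside the short tracking windows, so a single-beat template
only becomes unreliable — the failure mode that distinguishes
`n_sl = 1` from `n_sl = 15` — once noise overwhelms that lobe, while
deeper templates keep their √n_sl advantage.

## Known limitations

* The segment length `w` is frozen after initialization; records with
  large sustained heart-rate change need re-initialization (no adaptive
  RR tracking).
* No artifact removal: sustained artifacts longer than `n_sl` beats will
  carry the template away.
* MC and IM fiducials are not annotated.
* Offline only; the causal filter mode exists but the algorithm itself
  needs `n_it` beats before the first diastolic annotation.
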