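---
title: "Beat-to-beat fetal heart rate from Doppler ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat fetal heart rate from Doppler ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopplerfhr)
```

## The problem

Cardiotocographs determine the fetal heart rate (FHR) from the Doppler
ultrasound echo of the beating fetal heart. Because the echo has a complex
multi-phase structure — one burst per valve opening/closing and per wall
movement within each cardiac cycle — monitors estimate the *periodicity* of
the signal with an autocorrelation function (AF) rather than detect
individual beats, and they emit one smoothed estimate every 250 ms. Such an
evenly spaced series contains duplicate and averaged measurements: a single
cardiac interval is represented by several values, and each value averages
several intervals. Clinical indices of *short-term variability* (STV), which
quantify genuine beat-to-beat fluctuation, are then severely underestimated.

`dopplerfhr` implements a complete processing channel that turns the raw
demodulated Doppler waveform into a *time series of events* — exactly one
(τᵢ, Tᵢ) pair per cardiac interval, as an electrocardiogram would provide —
together with the evaluation machinery needed to score such a channel
against a reference beat series, and a synthetic-signal generator that makes
every stage testable with known ground truth.

## Signal model and the simulator

The demodulated Doppler signal is audio-band: heart-wall movements occupy
roughly 100–300 Hz and the faster valve movements 300–600 Hz. The simulator
(`generate_beat_times()`, `synthesize_us_signal()`) emulates:

* a ground-truth beat train whose instantaneous rate follows a baseline
  (60–240 bpm), optional long-term-variability sinusoids and trapezoidal
  acceleration/deceleration episodes, with iid Gaussian beat-to-beat jitter
  (`stv_jitter_sd_ms`) as the STV surrogate;
* per-beat multi-phase bursts: Gaussian-windowed sinusoids ("Gabor atoms")
  for the valve phases Mc, Ao, Ac, Mo (300–600 Hz) and wall phases Vc, Atc
  (100–300 Hz), placed at fixed fractions of the cycle after each onset
  (Mc 0.00, Vc 0.05, Ao 0.12, Ac 0.35, Mo 0.45, Atc 0.90). Real timing of
  the cardiac phases varies between fetuses and transducer positions; these
  offsets are a plausible ordering, not measured values, and are
  configurable;
* slow amplitude drift (transducer/fetus geometry), additive white noise,
  and movement-interference episodes (band-limited 10–80 Hz bursts
  uncorrelated with beats).

Defaults: sampling rate 3000 Hz (five times the top of the valve band; the
acquisition rate of real monitors is not critical as long as it clears
Nyquist for 600 Hz), `noise_sd = 0.03` relative to the strongest burst,
which yields an overall SNR of about 17 dB — a clean but not sterile
recording. Everything is deterministic given a seed.

What the simulator does **not** model: the 1 MHz carrier and demodulation
electronics, maternal ECG contamination, true physiological phase-timing
variability, and the heavy non-stationary interference of real labor
recordings. Tests passing on these signals therefore demonstrate
correctness of the algorithms under controlled conditions, not clinical
performance.

## Preprocessing

`bandpass()` separates wall (100–300 Hz), valve (300–600 Hz) or full
(100–600 Hz) bands with a 4th-order Butterworth applied forward–backward
(`signal::filtfilt`). Zero-phase filtering matters because the whole point
of the channel is millisecond-scale beat timing.

Two envelope paths reduce the bipolar echo to a unipolar envelope:
rectification followed by a zero-phase low-pass (cutoffs 25–150 Hz), or the
magnitude of the analytic signal (FFT construction) optionally smoothed by
an 11- or 21-sample moving average at the raw rate. Both paths resample to
a fixed 1 kHz envelope rate so that one autocorrelation lag equals 1 ms;
linear interpolation suffices because the envelope is already band-limited
well below 500 Hz. Tiny filter undershoot is clipped to zero (an envelope
is a magnitude by definition). The moving average is applied before
resampling, interpreting its length in raw signal samples.

## Periodicity measurement

`measure_instantaneous()` slides a window of width `D` (default 1 s) with
hop `K` (default 25 ms) and computes, per window, a mean-removed
autocorrelation normalized by its zero-lag value. The estimator is
*biased* (no per-lag renormalization): this makes the absolute amplitude
thresholds meaningful — a clean peak at lag 500 ms in a 1-s window reaches
about 0.5–0.9, pure noise stays below ~0.4 — and avoids the spurious growth
of unbiased estimates at long lags. The search range is the physiological
250–1000 ms (60–240 bpm), additionally capped at `D·1000 − 200` ms so every
candidate lag keeps at least 200 ms of overlap support. Argmax ties break
toward the shorter lag, which counters half-rate doubling on smooth wall
envelopes. Each measurement is stamped at the window end (causal).

Quality control: a window whose AF peak is below `P_TH = 0.1` emits a loss
marker. When the peak is between 0.1 and the gate 0.5, a *trapezoidal
prediction function* re-weights the AF before the argmax: weight 1 on a
plateau of width S/4 centred on the last reliable period, linear flanks to
zero at ±S/2 (base ratio 1:4), zero outside. A period found under
prediction is flagged and does **not** move the trapezoid centre for later
windows, so a run of predictions cannot drag the prior away. Loss marking
uses the pre-weighting amplitude. Outside the lower base the weight is
zero — the strongest suppression consistent with the trapezoid, needed to
actually overrule spurious peaks far from the prior.

A known numerical effect: when a burst straddles a window edge, its
truncated correlation contribution can bias the argmax by 1–2 ms on
noiseless multi-phase envelopes (more on sparse single-burst envelopes).
The segment medians and validation downstream absorb this.

## Event extraction

**D1 — duplicate correction.** The 25-ms stream is collapsed to the
250-ms monitor standard (`median_fhr_250()`: median of 10 consecutive
measurements, loss if more than half invalid, values quantized to the
0.25 bpm monitor resolution so duplicates repeat exactly). The even series
is then partitioned into maximal runs of identical values and each run of
`n` slots of value `T` is converted to events (`correct_duplicates()`):
the bracket `Min = (n−1)·250/T`, `Max = (n+1)·250/T` either agrees after
rounding (the unique consistent count) or the most probable count
`round(n·250/T)` is emitted, at least one event per run, laid consecutively
from the run start. Rounding is half-away-from-zero. Loss slots break runs
and leave gaps.

**D2 — segmentation of instantaneous measurements.** The analysis starts
at an RMS-derived point `P` (`find_starting_point()`): RMS of the envelope
in a sliding window (default 500 ms) over the first 3 s, then a backward
walk from the RMS maximum until it first drops below 2/3 of the maximum —
just before a strong cardiac burst. Plain segmentation
(`segment_measurements()`) accumulates valid measurements while their
running median `m` satisfies `n·25 ≤ m`, then emits `T = m`. With the
matching algorithm (`segment_with_maa()`, the default), each segment window
is bounded by the previously determined interval, the emitted `T` is the
median of the measurements inside it, and after each emission the agreement
between the last seven intervals and the measurement stream is scored for
timestamp shifts of ±25 ms (the repetition step γ); if a shifted overlay
matches strictly better, the next timestamp moves by the correction quantum
`|ε| = γ/5 = 5 ms` toward the winning shift. The correction sign is chosen
so that the overlay converges onto the stream — a constant planted offset
shrinks monotonically — and interval *values* are never altered by the
matching. Segments cannot span loss: a window without valid measurements
becomes a gap and segmentation resumes at the next valid measurement.

## Validation

`validate_events()` flags implausible intervals without altering any value.
The acceptance corridor around the previous interval is
`(T_prev − 0.1·Δ, T_prev + 0.15·Δ)` with `Δ = T_prev − 300 ms` above the
320 ms breakpoint and `Δ = 20 ms` below it (open interval). The corridor
anchor is the last interval that itself met the corridor, so one artifact
does not poison the comparison for its successors — and a stretch of
mutually consistent artifacts is still judged against the last good value.
A directional pass accepts its meeting intervals provided it found at
least three of them. The backward pass repeats the procedure on the
reversed series with the asymmetric fractions swapped (the "change of
thresholds"; configurable off), and an interval is classed incorrect only
when **both** passes reject it — this protects genuine monotone
acceleration/deceleration ramps. Finally, intervals still classed
incorrect are confirmed only if the differences with both neighbours have
the same sign and their product exceeds 35 ms²; otherwise they are
rehabilitated. Validation is idempotent.

## Evaluation methodology

`synchronize()` finds the displacement of a test series relative to a
reference over ±3000 ms in 1-ms steps. The objective is the time-integrated
`|T_test(t) − T_ref(t)|` over the 5–55 s analysis window: the two interval
step functions are overlaid at each shift and the integral of their
absolute difference accumulated where both are valid. This objective is
alignment-sensitive at sub-interval scale, so a planted shift on a clean
series is recovered exactly; sampling only at interval midpoints is
piecewise constant in the shift and cannot resolve alignment finer than
about half an interval. Ties break toward the smallest absolute shift.

All reported error statistics are midpoint-sampled: each reference interval
whose midpoint lies in the window is paired with the test interval
containing the (shifted) midpoint; `interval_errors()` reports the mean, SD
and mean absolute ΔT over these pairs. Signal loss is time-weighted: the
percentage of the window not covered by valid test intervals, so a 1-s gap
in the 50-s window costs exactly 2%.

Twelve variability indices (six STV, six LTV, named for Dawes, Yeh,
de Haan, Zugaib, Huey and Dalton) are computed over valid intervals in the
window. The canonical historical formulas are scattered across decades of
obstetric literature; this package ships *operational* definitions (mean
absolute successive difference, epoch-based Dawes variants on 3.75-s
epochs, the Yeh differential index, de Haan's interquartile measures, and
so on — see `?variability_index_registry`) in an exported registry, so a
user with the original definitions can substitute them index by index.
Difference-based sums never span a loss gap. With fewer than 10 valid
intervals the indices are reported missing, never zero. Relative errors
are `(test − ref)/ref · 100` per index.

`render_monitor_series()` closes the loop: it re-renders an event series
the way a classical monitor would see it (trailing 1-s averaging window,
250-ms slots, 0.25 bpm quantization), which is how the package demonstrates
the central phenomenon — averaging and duplication systematically shrink
every STV index, while the D2 event series preserves them.

## Problem sizes and reproducibility

The test-suite and acceptance studies use 60-s records at 3 kHz (about 120
beats) with 120 bpm baseline and 5-ms beat-to-beat jitter, ten seeds for
the ground-truth recovery study and three seeds for each directional trend
(window-width effect, matching on/off). These sizes give stable estimates
of millisecond-scale means while keeping a full run in a few minutes. On
such signals the default channel (valve band, Hilbert + MA21 envelope,
D = 1 s, K = 25 ms, prediction S = 500 ms, D2 with matching, validation on)
achieves a mean absolute interval error of about 1 ms with signal loss
around 0.5% — the numbers printed by the README example are produced by
exactly this configuration. Every random stage takes an explicit seed and
identical seeds give bit-identical waveforms, measurements and reports.

## Known limitations

* The phase-timing offsets and index formulas are declared operational
  choices (see above), not literature-exact reproductions.
* The biased AF argmax can be 1–2 ms off for windows that clip a burst at
  their edge; this is visible in noiseless unit tests and absorbed by the
  segment median in practice.
* The validation's group-of-three and backward "change of thresholds" are
  under-determined in the clinical literature; the implemented reading
  (anchor-skipping corridor, swapped fractions, both-direction rejection)
  is documented above and configurable where ambiguous.
* Clinical-grade performance claims require real co-recorded
  Doppler/FECG material, which this package deliberately does not include.
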