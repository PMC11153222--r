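---
title: "Real-time EEG seizure detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time EEG seizure detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtseizure)
```

## The detection problem

Epileptic seizures appear in scalp EEG as spike and sharp-wave discharges
with elevated rhythmic power, most discriminably in the 20-60 Hz range.
`rtseizure` implements a real-time detection pipeline for multichannel
scalp EEG in the CHB-MIT recording convention (256 Hz, bipolar montage):

1. select six bipolar channels near the frontal, temporal and occipital
   onset zones (P3-O1, FP2-F8, P8-O2, P7-T7, T7-FT9, FT10-T8);
2. band-pass 1-60 Hz with a zero-phase Butterworth filter;
3. slide a 1.35-s window (345 samples) with 1-s overlap over the
   recording; per window and channel, compute a short-time Fourier
   transform restricted to 20-60 Hz and stack the six 20 x 344 log-power
   blocks into one 120 x 344 image;
4. classify each image with a 29-level GoogLeNet-style inception CNN into
   seizure-active vs seizure-free;
5. turn per-window decisions into seizure events, scored by event
   sensitivity, window false-positive rate, detection delay and accuracy.

"Real time" means causal sliding-window processing: every decision uses
only the samples of its own window, so truncating a recording reproduces
all decisions whose windows still fit (`stream_detect()` has a test for
exactly this property).

## Preprocessing

`filter_spec()` defaults to an order-6 Butterworth band-pass, 1-60 Hz.
"Order 6" follows the `butter(n, [lo hi])` convention of the tooling this
pipeline descends from: the low-pass prototype has 6 poles and the
band-pass transform doubles them, i.e. a 12-pole filter realized as six
second-order sections. The design is closed-form (analog prototype poles,
prewarped low-pass-to-band-pass transform, bilinear transform, conjugate
pairing into sections) and `butterworth_magnitude()` exposes the analytic
magnitude the design must match; the test suite verifies agreement to
1e-6 and a stop-band attenuation of more than 36 dB above 80 Hz after the
two passes.

Zero-phase filtering applies each section forward and backward with
odd-reflection edge padding. The padding length is adaptive - long enough
for the slowest pole to decay below 1e-9 (about 13 s at the 1 Hz edge) -
because a fixed short pad leaves visible edge transients at this order.
Whole recordings are filtered before windowing, so the 1.35-s analysis
windows never see filter edges.

One caveat worth stating: a Butterworth band-pass has half-power points
*at* its edges, so in-band (1-60 Hz) white-noise energy is preserved only
to about 94% after the forward-backward pass; the loss is concentrated in
the last few Hz below 60. The test suite asserts preservation within 10%,
which is what this filter family can honestly deliver with edges at 1 and
60 Hz.

## Spectrogram features

`stft_params()` defaults are taken literally from the pipeline's
published parameterization: a 2-sample Hamming window (both taps 0.08),
1-sample hop, zero-padded to a 128-point transform (2 Hz bin spacing at
256 Hz), magnitudes squared and converted to dB. This is the only reading
that produces 344 frames from a 345-sample window and 20 rows in
[20, 60) Hz, hence the 120 x 344 epoch with 41,280 values. Values are
floored at -120 dB so silent windows stay finite; scaling the input by 10
raises every above-floor value by exactly 20 dB.

A consequence of the 2-sample window is worth understanding: each frame
holds two samples, so the transform behaves as a 2-tap filterbank whose
mean bin power is `P (1 + r1 cos(2 pi k / 128))` with `r1` the lag-1
autocorrelation. Within-band frequency selectivity is therefore minimal -
the features encode broadband 20-60 Hz power and short-lag correlation
rather than a sharp spectral line. That is sufficient for the detection
task (seizures raise in-band power broadly), and the implementation is
verified against a brute-force zero-padded DFT of every frame; but a
tone-localization test needs a longer window (the suite uses 64 samples)
to be meaningful. Band edges are half-open `[low, high)`: 20-60 Hz yields
exactly 20 bins, a closed interval would yield 21.

With the default 1-sample STFT hop, the per-channel spectrogram of a
whole recording is computed once and sliced per window
(`extract_epochs()`); this is exactly equal to transforming each window
separately and roughly 300 times cheaper.

Windows are labeled seizure-active when at least half the window (default
`min_overlap_frac = 0.5`) overlaps an annotated interval; intervals are
closed at onset, open at offset, making boundary-window tests
unambiguous.

## The network

`default_architecture()` is the 29-level inception network for
120 x 344 x 1 inputs: three stem convolutions (5x3, 5x3, 1x1; 64, 64, 192
channels; no padding), five ceil-mode max-pools, nine inception blocks
(output channels 256, 480, 512, 512, 512, 528, 832, 832, 1024), a 7x7
average pool, 40% dropout and a 2-class fully connected + softmax head.
Inception blocks count as depth 2 - the convention that makes the final
fully connected layer level 29. Padding is forced by the shape table:
valid for the stem (120 x 344 -> 116 x 342), same inside inceptions
(spatial sizes preserved), and ceil-mode pooling (112 -> 56 with a 3x3
stride-2 pool requires padding the overhanging edge). Branch channel
allocations inside the inceptions are the canonical GoogLeNet ones, which
reproduce the published block totals exactly; `shape_trace()` recomputes
the whole table from the rules and the suite freezes every row.

Every convolution is followed by batch normalization and ReLU. Because no
deep-learning framework exists in this package's dependency footprint,
the network runs on a small engine written in base R: convolutions are
im2col gathers followed by one BLAS matrix multiplication, pooling and
batch-norm are vectorized, and gradients for every unit (including the
four-branch inception blocks) are verified against central finite
differences in the test suite.

Training (`train_model()`) is mini-batch SGD with momentum 0.9, learning
rate 0.01, 30 epochs by default, 2-class cross-entropy, a stratified 20%
validation hold-out and validation accuracy recorded every 50 iterations.
Inputs are zero-centered by the scalar mean of the training epochs,
stored in the model and applied at inference. After the last iteration
the batch-norm running statistics are replaced by population statistics
computed over the full training set - without this, models trained for
few iterations classify at chance in inference mode even when training
accuracy is perfect (the momentum-0.9 running averages have not
converged). Optional inverse-frequency class weights are off by default.
All randomness (initialization, split, shuffling, dropout) flows from
explicit seeds; repeated runs are bitwise identical.

The training protocol for annotated recordings takes, per seizure, the
raw EEG from 10 minutes before to 5 minutes after onset (clipped to the
recording, merged when seizures are close), and the leave-one-subject-out
helpers hold each subject out once.

## Event scoring

`extract_events()` matches each annotated interval to the first
asserted-positive window whose start lies in
`[onset - pre_tolerance_s, offset)`; the window's start time is the
detection time (the earliest causally defensible claim) and
`delay = detection time - onset`. By default `pre_tolerance_s = 0` (a
detection must fall inside the annotated interval; delays are
nonnegative) and `smoothing_k = 1` (no decision smoothing) - both exposed
because evaluation conventions differ on crediting pre-onset detections.
At most one true positive is credited per seizure; further positives
inside a matched interval are neither hits nor false alarms; runs of
positives outside every interval are grouped into false-positive events.
The implementation is checked against an exhaustive-interval oracle on
500 random configurations.

Window-level metrics follow the standard ratios: accuracy
`100 (TP+TN) / total`, false-positive rate `100 FP / (FP+TN)` (the only
reading on the same percent scale as published per-patient tables; some
literature instead reports FP/hour), and event sensitivity
`100 detected / seizures` reported to two decimals with half-up rounding.
Pooling averages FP rate, accuracy and delay over cases (delay over cases
with at least one detection) and computes sensitivity from summed counts.

## Synthetic EEG

`generate_recording()` emulates the statistical structure the pipeline
relies on, not clinical realism: per-channel 1/f background (default
15 uV RMS) plus a 10 Hz rhythm (10 uV, random phase), and seizure
episodes made of periodic sharp transients at 3-5 Hz plus band-limited
20-60 Hz noise. The band noise variance is calibrated per channel so that
total in-band seizure power exceeds the channel's background in-band
power by the configured `band_boost_db` - the spike train's own in-band
contribution is measured and subtracted first, which keeps the realized
boost within a fraction of a dB of the setting (verified against an
independent averaged-periodogram oracle at 6, 12 and 20 dB). Seizure
components hit all channels with gains in [0.5, 1]; background noise is
independent per channel. Amplitude-depression onsets - which this
detection approach does not target - are not generated unless a seizure
row sets `depression = TRUE` (useful for negative tests).

Because the generator plants a broadband 20-60 Hz power elevation, it
exercises exactly the feature the detector uses. Passing the end-to-end
gate therefore demonstrates that the pipeline's plumbing, features,
training and scoring work together - it does not demonstrate clinical
performance on real EEG, where seizure signatures are weaker, artifacts
abound, and inter-subject variability is far larger.

## Desk-scale study conditions

The default synthetic study is 3 subjects x 480 s, three 35-s seizures
per subject at 20 dB boost (nine seizures total). At these sizes the
end-to-end leave-one-subject-out experiment trains on roughly 900 epochs
per fold (every third window of the peri-ictal segments) and runs in a
few minutes per fold on one CPU with the narrow `reduced_architecture()`
(width 8, two inception blocks, a strided first convolution) and 3
training epochs - ample for the strongly separable synthetic classes,
whose validation accuracy saturates within the first epoch. The full
Table-sized network is built and traced in the tests and runs forward in
seconds, but training it is a GPU-scale undertaking by design and is not
part of the desk-scale study.

## Numerical choices and degenerate inputs

* Spectrogram floor -120 dB; all-zero windows produce all-floor epochs.
* Recordings shorter than one window yield zero windows/decisions, not
  errors; filtering requires enough samples for the edge padding.
* Average pooling requires exact tiling (the 7x7 pool meets a 7x7 map);
  ceil-mode max pooling pads only the overhanging edge with -Inf.
* Ties in the softmax argmax resolve to the first class (seizure-free).
* Training aborts with a diagnostic on non-finite loss; single-class
  training sets are rejected.
* EDF output quantizes to 16 bits over a symmetric per-channel physical
  range; round-trips are exact to one quantization step.

## Known limitations

* The detector inherits the method's stated blind spot: seizures whose
  onset is an amplitude depression are invisible to a band-power
  detector.
* The 2-sample STFT window makes the features nearly frequency-blind
  within the band (see above); richer spectral structure would need a
  longer window and a different published parameterization.
* FP-rate is window-based; FP/hour reporting would need the recording
  durations kept alongside.
* The engine is CPU-bound base R; it is meant for desk-scale experiments
  and architecture verification, not full-database training.
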