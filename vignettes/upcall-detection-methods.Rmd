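---
title: "Detecting right whale upcalls with small deep networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting right whale upcalls with small deep networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

North Atlantic right whales announce their presence acoustically with the
*upcall*: a stereotyped tonal contact call that sweeps upward in frequency,
lasting roughly 0.5–2 s and starting its sweep somewhere between about 55
and 157 Hz. Passive acoustic monitoring archives contain months of
continuous low-frequency recordings per sensor, far more than analysts can
audit directly, so detection is automated and analysts verify the
detector's output. The operational constraint is not raw accuracy but the
review bill: an experienced analyst can verify roughly 2,000 detections per
working hour, and in our framing a detector is field-usable when it
produces fewer than about 20 false positives per recording hour at a
useful recall. `upcallr` implements the full workflow — featurization,
training-set construction, small neural classifiers, sliding-window
detection, and review-cost evaluation — together with a synthetic
soundscape generator so every stage is testable without field recordings.

## Features: the 40x40 spectrogram patch

The classifier's input is a 2 s clip at 2 kHz, transformed with a 128 ms
Hann window advanced by 50 ms, keeping 40 FFT bins starting at bin 5 of
the 256-point transform (bin width 7.8125 Hz, so kept-center frequencies
run 39.0625–343.75 Hz). That band covers the upcall fundamental with room
above and below.

Two framing details are deliberate:

* **Frame count.** Frames start at 0, 50, ..., 1950 ms, so a 2 s clip
  yields exactly 40 frames, with the last two windows running past the
  clip end and zero-padded. The conventional `(N − W)/hop + 1` count
  would give 38 frames and a non-square patch; the square 40x40 geometry
  is the contract everything downstream assumes.
* **Bin range.** The 40 bins are bins 5–44. Bin 5 is 39.0625 Hz; the top
  kept center is 343.75 Hz. A nominal upper edge near 357 Hz does not
  fall on the 7.8125 Hz grid, so the bin indices, not a rounded
  frequency, are the normative definition.

Magnitudes are linear, not dB. Two normalizations are provided:

* `sum_square` — each element divided by the sum of squared elements
  (`x / sum(x^2)`), the literal matrix normalization this patch design is
  described with. It is **not** gain-invariant: scaling the waveform by
  `c` scales the normalized patch by `1/c`.
* `unit_frobenius` — division by `sqrt(sum(x^2))`, giving Frobenius norm
  1 and full gain invariance.

`normalize_patch()` defaults to the literal `sum_square`. The pipeline
(`run_config()`) defaults to `unit_frobenius`, for two reasons. First,
gain invariance is the evident *intent* of an energy normalization in a
detector that must generalize across recorders and propagation losses.
Second, at the data scales of our synthetic experiments the literal
formula maps patches to elements of order 1e-5, which leaves a
tanh-activated network with near-zero logits and no usable training
signal within the small update budgets used here; the Frobenius variant
puts patch energy at a fixed, healthy scale (elements of order 1/40).
Both modes are first-class and a trained scorer records which one it was
trained with; scoring always re-applies the scorer's own mode.

## Training sets

Positives are 2 s clips starting 1 s before the temporal midpoint of each
annotated call, so the call is centered in the patch. Random negatives
are drawn uniformly from call-free time, where "call-free" means the 2 s
window dilated by a guard interval (default 1 s) touches no annotation —
the guard prevents near-miss leakage of call energy into the background
class. Augmentation re-cuts each clip with its start shifted by an
amount drawn uniformly in ±200 ms and pools the shifted copies with the
originals; shifting happens in the waveform, not the patch, so edge
content is real audio.

Hard-negative mining closes the loop: a preliminary model is run as a
detector over the training streams, and detections scoring at least 0.5
that fall on no annotation (within the evaluation tolerance) are added to
the training pool as `hard_negative` background examples. Candidates
within 0.1 s (one detector hop) of a negative already in the pool are
dropped, operationalizing "not already in the training set". A detection
overlapping a true call is never mined, even when one-to-one matching
would label it a false positive — a duplicate detection of a real call is
the wrong thing to teach the background class with. Stage-2 training
starts from fresh random initialization rather than fine-tuning the
stage-1 weights.

Unstated multiplicities were fixed once: one augmented copy per example,
and random negatives at 0.8 per positive by default (mirroring the
roughly 5.5k negatives to 6.9k positives balance of the reference
training pools).

## Classifiers

Two architectures are registered; both take the 40x40 patch and emit a
two-way softmax (the upcall-class probability is the detector score).

**`lenet_variant`** — dropout on the input; 5x5 convolution with 32
filters, tanh; 2x2 max-pool; dropout; 5x5 convolution with 64 filters,
tanh; 2x2 max-pool; dropout; a 500-unit fully-connected tanh layer; and
the 2-way softmax. Max pooling replaces the classic average pooling and
tanh is used in place of ReLU (a config switch restores ReLU). Kernel
size 5x5, the 500-unit width, and dropout probability 0.2 at every
dropout site are this package's choices where the classic design leaves
them open; 0.2 matches the one dropout probability stated in the lineage
this family of detectors comes from.

**`crnn`** — a 1-D convolution along time (the 40 frequency bins are the
input channels; 64 filters of kernel length 3), batch-normalized, ReLU,
dropout; two GRU layers of width 64, each batch-normalized; the final
time-step state feeds the softmax.

Training minimizes class-weighted categorical cross-entropy with Adam.
Defaults follow the reference protocol: batch size 1,000, 100 epochs,
positive examples weighted 3x to counter class imbalance, and a
learning-rate decay of 0.005 interpreted as per-update inverse-time decay
(`lr_t = lr0 / (1 + 0.005 t)`); the base rate defaults to 1e-3 (the Adam
convention, unstated in the protocol). All stochastic choices —
initialization, shuffling, dropout masks — flow from one seed, and
training is bit-reproducible given it. `train_replicates()` trains `n`
instances from consecutive seeds (default 10) so downstream metrics can
be reported as means over random initializations.

The network code is written directly on R matrix operations with the
im2col/pooling data movement and a fused LeNet inference path in C++;
gradients for every layer (convolution, pooling, batch norm, GRU) are
validated against central finite differences in the test suite. The
fused inference path is bit-identical to the modular forward pass and
exists because sliding-window detection evaluates the network once per
0.1 s of audio.

## Detection

`score_stream()` advances a 2 s window by 0.1 s, featurizes each window
exactly as in training (including the zero-padded trailing frames of
each clip — a window is featurized in isolation, never sliced from a
global spectrogram), and scores it. `non_max_suppress()` reduces the
dense score track greedily: repeatedly take the highest remaining score
at or above the floor (default 0.05), emit a detection at that window's
center, and suppress all windows whose centers lie within the radius.
The suppression radius defaults to 1 s — half the window length and
about one call duration; the floor is part of the reference protocol,
the radius is this package's choice and is configurable. Ties break
toward earlier time; lowering the floor never removes a detection a
higher floor produced.

## Evaluation

A detection may match an annotation iff its peak time lies within the
annotation dilated by a tolerance (default 0.5 s); assignment is greedy
by descending score and one-to-one, so `TP + FN` equals the number of
annotations and `TP + FP` the number of detections. The matching rule is
this package's definition (reference scoring rules for this task are not
published in reusable form); the tolerance is exposed so other
conventions can be emulated. Precision is `TP/(TP+FP)`, recall
`TP/(TP+FN)`; degenerate denominators are flagged as undefined, never
silently zero. The PR curve sweeps the sorted unique scores and average
precision is the step-wise area `sum((R_i − R_{i−1}) P_i)` — standard
for detection tasks and conservative relative to trapezoidal
interpolation. `recall_vs_fph()` reports the operating curve against the
false-positive budget, and `workload()` turns an operating point into
analyst hours at the 2,000-detections/hour review rate.

## The synthetic soundscape generator

`render_scene()` builds annotated scenes: band-limited (10–800 Hz)
Gaussian noise with power ∝ 1/f (slope configurable; pink-ish ambient is
the default because low frequencies dominate ocean noise), upcalls as
Hann-enveloped upsweeps with start frequency U(55, 157) Hz, duration
U(0.5, 2) s, bandwidth U(60, 120) Hz and curvature exponent U(0.8, 1.5),
and four confounder families (downsweeps, flat tones, broadband pulses,
and near-miss upsweeps outside the call envelope) that exist precisely
to stress the detector the way real interfering sounds do. Call and
confounder onsets are independent Poisson processes (defaults: 60/h
each); calls are redrawn rather than allowed to overlap one another.
Each call is scaled so its SNR — defined over the call's own time
support and the 39.06–343.75 Hz analysis band, since broadband SNR would
be dominated by noise the classifier never sees — hits the target
(default 10 dB). Scenes are bit-reproducible from their seed.

What the generator does *not* emulate: propagation and multipath,
calibrated absolute levels, non-stationary ambient (shipping, weather),
real humpback song, and annotation error. Passing tests on synthetic
scenes therefore demonstrate that the machinery is correct and that the
two-stage protocol behaves as designed — not that field performance on
any particular archive is reproduced.

## Scaled-down experiment design

The package's self-tests run two end-to-end experiments sized for a
single CPU:

* **Recovery.** Train the `lenet_variant` (batch 64, 15 epochs) on a
  30-minute scene with calls at 120/h (yielding a pool of roughly 500
  examples after augmentation, with negatives at 3 per positive) at
  10 dB in-band SNR, then detect on a held-out 30-minute scene at the
  default 60 calls/h. The check is the operational one: recall at the
  ≤ 20 FP/h operating point.
* **Mining benefit.** On confounder-rich 8-minute scenes (confounders at
  240/h, SNR drawn from 6–12 dB, batch 64, 8 epochs), the stage-2 model
  should match or beat the stage-1 model's average precision in a
  majority of five seeded runs.

These sizes are the package's chosen desk-scale study conditions; the
full-scale protocol (batch 1,000, 100 epochs, multi-day training data,
ten replicates) remains the default configuration of `train_config()`
and `run_config()`.

## Numerical and degenerate-input choices

* Zero-energy patches are returned unnormalized with a warning flag
  rather than divided by zero; zero-energy windows are never mined as
  hard negatives.
* Audio resampling is FFT-domain with a raised-cosine anti-alias rolloff
  (unity to 0.82x the new Nyquist, zero from 0.9x) when down-sampling —
  the passband geometry of a practical decimator rather than a razor
  edge at Nyquist.
* Max-pool ties break to the first element in block scan order;
  NMS ties break to earlier time; both are fixed so runs are exactly
  reproducible.
* Annotations closer than 1 s to a stream edge produce zero-padded,
  flagged clips instead of errors; fully-outside annotations error.
* Pipeline stages derive their seeds from one global seed through named
  substreams (`derive_seed()`), so a stage can be re-run in isolation.

## Known limitations

* The literal `sum_square` normalization is supported but not
  recommended for training at small data scales (see above).
* The GRU/batch-norm stack runs in plain R and is an order of magnitude
  slower than the fused LeNet path; the `crnn` is practical for patch
  classification experiments, less so for scoring hours of audio.
* The evaluation matcher is single-stream; cross-sensor fusion and
  per-channel aggregation are out of scope.
* Scores are probabilities under the trained softmax but are not
  calibrated; threshold choices should come from the
  `recall_vs_fph()` curve, not from reading scores as frequencies.
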