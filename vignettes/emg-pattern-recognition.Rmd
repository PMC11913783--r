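---
title: "Methods: EMG pattern recognition at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG pattern recognition at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgpr)
```

emgpr re-implements, in software only, the control stack of a
pattern-recognition myoelectric prosthetic hand: three channels of
forearm surface EMG are turned into spectral features, a small neural
network decodes the intended motion each 10-ms frame, and a ring-buffer
vote stabilizes the output stream. This vignette documents the model,
the parameters that matter, what the synthetic generator does and does
not emulate, and the numerical and design choices made where the
underlying system left them open.

## The measurement model

The acquisition chain is emulated as configured on the target hardware:
2,000 Hz sampling, a ±2.5 V range quantized at 12 bits, an analog front
end consisting of a band-pass filter and a 50-Hz notch (mains power in
eastern Japan runs at 50 Hz), and a software 50-Hz high-pass. Two
details deserve comment.

* The hardware band-pass is described in two places with different
  corner frequencies (1–1,000 Hz in the settings table, 10–400 Hz in the
  sensor description). The generator uses 10–400 Hz, which matches the
  described sensor amplifier; essentially all synthetic signal energy
  lies inside both bands, so the choice is not load-bearing.
* The software 50-Hz high-pass sits *above* the two lowest selected
  feature frequencies (23.4375 and 46.875 Hz), which it therefore
  attenuates strongly. This tension is preserved rather than resolved:
  both stages are implemented exactly as configured, the high-pass is on
  by default, and it can be disabled with
  `spectral_config(softfilter_hz = NULL)`. In practice the remaining six
  frequencies carry ample class information and held-out recognition is
  unaffected.

The ADC maps a voltage to `round((v + 2.5)/5 * (2^12 - 1))`, clipped to
the code range; this fixed affine convention makes quantization
bit-exactly testable, and the maximum in-range error is half a step.
Quantization is an explicit operation (`quantize_adc()`), not a property
of file I/O: recordings store voltages as doubles.

## Feature extraction

Each channel is framed at 256 samples with 236 samples of overlap — a
20-sample hop, hence a 10-ms frame period — tapered with a Hann window,
and transformed with the FFT. "Frequency components" are taken as the
one-sided, unnormalized amplitude spectrum `|X[k]|`: amplitude (rather
than power) keeps the features homogeneous of degree one in the input,
which is both conventional for EMG features and easy to test. For each
selected frequency, whose bin index is `b = f * 256 / 2000`, the feature
is the mean of bins `b - 2 … b + 2` (the "5 points" smoothing read as a
centered window; the lowest selected bin, 3, keeps the window in range).
Features are concatenated channel-major into a 24-vector, matching the
network's input layer. Frames that would run past the end of the
recording are dropped (streaming semantics, no padding); a recording
shorter than one frame yields an empty result with a warning rather than
an error, since a streaming caller may simply not have data yet.

The mean absolute value (MAV), the rectified per-window amplitude shown
to the user during labeling, is provided as `compute_mav()` and is used
by the tests as a coarse activity oracle.

## Classifier and training

The network is a 24–32–8 multilayer perceptron with sigmoid activations
at both the hidden and output layers, trained by plain gradient descent
at learning rate 0.01 on the sum-of-squared error against one-hot
targets — the era- and hardware-appropriate choice for a 200-MHz
microcontroller, rather than softmax/cross-entropy. Choices the
underlying description leaves open:

* **Normalization.** Raw spectral amplitudes saturate sigmoids, so
  features are min–max scaled to [0, 1] with ranges computed on the
  teacher set and stored with the weights (zero-range features scale by
  1). The same transform is re-applied at prediction time.
* **Initialization.** Weights start uniform in [−0.5, 0.5] from a seeded
  RNG; training is exactly reproducible given the seed.
* **Batching and epochs.** Default is full-batch descent for 500 epochs;
  per-sample (online) updates in fixed order are available via
  `batch = "sample"`. On the default fixtures the full-batch loss trace
  is monotone non-increasing and training completes in well under a
  second.
* **Class slots.** With `|Y| < 8` motions only the first `|Y|` output
  units are trained and consulted, in ascending motion-id order; rest is
  an ordinary class. More than 8 classes is an error.
* **Teacher count.** The number of frames buffered per class during
  labeling is not specified anywhere; the default is 100 frames (one
  second of frames per motion), exposed as `frames_per_class`.

Predictions take the argmax over assigned output units; exact ties break
toward the smallest motion id, a deterministic rule chosen so the filter
and classifier are exactly testable (an alternative, "most recent
winner", would be equally defensible but is not implemented).
Parameters serialize to JSON with 17 significant digits, so a saved and
reloaded model reproduces bit-identical scores — the software analogue
of the controller's EEPROM image.

## Recognition stabilization

The stabilizer keeps the last `N` predictions in a FIFO ring buffer and
outputs the most frequent class, ties toward the smallest id. During
warm-up the vote runs over however many entries are present, because a
prosthetic controller must emit a motion every frame; the first
prediction therefore passes through unchanged. `N` defaults to 15
(~150 ms at the 10-ms frame period), inside the 100–200 ms latency
budget conventional for myoelectric control; the value is configurable
and never hard-coded downstream. The printed update rule removes the
`t − N + 1`-th element after inserting the newest, which read literally
is off by one; it is implemented as a standard capacity-`N` FIFO.

## The synthetic generator

Surface EMG is approximated as band-limited Gaussian noise: per motion
and channel, white noise is shaped by a 4th-order Butterworth band-pass
to the class band (default bands sit inside 20–200 Hz, where most
surface-EMG energy lives), normalized to unit RMS, modulated by a
log-normal envelope drawn once per 10-ms frame, and scaled to the
class's per-channel RMS gain. Motions differ by their channel-gain
patterns; the default rest/grip/open/pinch set uses near-orthogonal gain
vectors with a 20-mV common baseline for rest, mirroring the three-to-
four-motion repertoires that are practical clinically. Gains are kept
near 0.5 V RMS so that the ±2.5 V ADC range clips only rare peaks.
A 50-Hz sinusoid models mains pickup, and the analog front end is
applied causally (an analog filter is causal), which also guarantees
that an electrode shift at time `t` leaves all samples before `t`
bit-identical.

Electrode shift — the covariate drift caused by socket reattachment or
perspiration — is modelled as a linear remix of the channel-gain
vectors from a given onset: identity leaves the session untouched, a
permutation swaps electrode positions, a scaled identity models
uniform conductivity loss. `apply_shift()` regenerates the session from
its stored script and seed, so shifted and unshifted sessions share the
same noise realization.

What the generator does **not** emulate: motor-unit action-potential
trains and their firing statistics, force-dependent spectral
compression, muscle fatigue, crosstalk dynamics, socket pressure, or
amputee-specific signal statistics. Passing tests therefore demonstrate
that the decoding stack is implemented correctly and behaves as designed
under its own signal model — not that the same accuracy would be
obtained on human recordings: recognition rates quoted for comparable
real systems come from human EMG that synthetic sessions cannot stand in
for.

## Pipeline and evaluation

`run_pipeline()` derives independent stage seeds from one master seed
(by drawing five integers from a seeded RNG), generates a labeling
session (default 1.5 s per motion) and a disjoint evaluation session
(two 1-s visits per motion), trains, and scores the evaluation stream
frame by frame. Frames whose 256-sample analysis window straddles a
label boundary are excluded from scoring — a window mixing two motions
has no single true label — and the stabilizer is reset at segment
boundaries, mirroring per-trial use. Reports carry the confusion matrix
(rows = true), overall and per-class recognition rates, and both pre-
and post-stabilizer rates; `report_json()` renders them byte-identically
for reproducibility checks. The post-stabilizer rate exceeding the
pre-stabilizer rate is an empirical property of these noisy fixtures,
not a theorem; the tests assert it only on fixtures sized to make
sampling error negligible.

Problem sizes throughout (6-s training sessions, 8-s evaluation
sessions, 100 teacher frames per class, 50,000-step flip-noise streams)
were chosen so every property is measured with comfortable statistical
margins while the whole suite runs in well under a minute.

## Known limitations

* The signal model is phenomenological; see above for what it omits.
* Only the Hann taper is implemented, and selected frequencies must lie
  exactly on the FFT grid — off-grid configuration is an error rather
  than an interpolation.
* The stabilizer implements plain majority voting only; confidence
  weighting and rejection thresholds are out of scope, as are the
  hardware motion-lock switch and all mechanical aspects of the hand.
* No online/incremental relearning: the drift experiment retrains from
  scratch on post-shift teacher data, which is what the deployed system
  requires of its users.
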