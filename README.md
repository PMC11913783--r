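# emgpr

Surface-EMG pattern recognition for myoelectric prosthetic hand control,
re-implemented as a desk-scale R package. It is aimed at researchers and
engineers who work on EMG-driven prosthetic controllers and want the full
decoding stack — spectral feature extraction, teacher-data labeling, a
small neural-network classifier and an output-stabilization filter — as
reusable, tested functions, together with a seeded synthetic EMG generator
so every stage runs without hardware or human recordings.

## The decoding stack

Three forearm EMG channels are sampled at 2,000 Hz with 12-bit
quantization over ±2.5 V. The feature extractor slides a 256-sample
Hann window along each channel with 236 samples of overlap (20-sample hop,
10-ms frame period), takes the one-sided amplitude spectrum, and extracts
8 center frequencies per channel (23.4375 … 312.5 Hz, all exact multiples
of the 2000/256 = 7.8125 Hz bin width), each smoothed as the mean of the 5
bins around its index. The resulting feature vector

x_t ∈ R^24, D = 3 channels × 8 frequencies

feeds an artificial neural network with 32 sigmoid hidden units and
8 sigmoid output units, trained by plain gradient descent (learning rate
0.01) on the sum-of-squared error against one-hot targets, over teacher
data {(x, y)} collected by pairing feature frames with the motion label
the user holds down. The per-frame prediction ŷ_t is then stabilized by
a ring buffer B_t of the last N predictions:

B_t ∪ {ŷ_t} → B_t,  B_t \ {ŷ_{t−N+1}} → B_t,  o_t = argmax_{i∈Y} f_i(B_t)

where f_i counts class i in the buffer; ties break toward the smallest
motion id. The synthetic generator emulates the analog sensor chain
(band-limited Gaussian noise per motion-specific channel-gain pattern,
50-Hz mains pickup, a 10–400 Hz band-pass with 50-Hz notch, ADC
quantization) and electrode-shift perturbations that remix channel gains
mid-session — the covariate drift that forces prosthetic users to relearn.

## Worked example

```r
library(emgpr)

ses <- generate_session(default_motion_specs(),
                        session_script(1:4, duration_s = 1.5, seed = 7))
ses$recording
#> <emg_recording: 12000 samples x 3 channels, 2000 Hz, 6.000 s>

rep <- run_pipeline(pipeline_config(seed = 7))
rep
#> <emg_eval: 704 frames, recognition rate 1.000 (pre-stabilizer 1.000)>
#>     predicted
#> true   1   2   3   4
#>    1 176   0   0   0
#>    2   0 176   0   0
#>    3   0   0 176   0
#>    4   0   0   0 176

rep$fit
#> <emg_ann: 24-32-8 sigmoid MLP, 4 classes (1,2,3,4), 500 epochs full, final SSE 0.4395>
```

`run_pipeline()` simulates a labeling session and a disjoint evaluation
session, collects 100 teacher frames per motion, trains the network, and
streams the held-out frames through prediction and the N = 15 vote filter.
The report above says all 704 scored evaluation frames of the default
rest/grip/open/pinch scenario were recognized correctly, before and after
stabilization. `relearning_experiment()` adds the electrode-shift arms: a
channel-swap shift drops the frozen model to 50% recognition, and
retraining on post-shift teacher data restores 100%.

`autoplot()` methods exist for recordings, fitted networks and evaluation
reports; `tidy()`/`glance()` give tabular summaries. A thin CLI is
installed under `exec/`: `emgpr simulate|run|drift --seed 7 --out …`.

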