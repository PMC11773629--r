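---
title: "Grid-free neural speech decoding: model, training, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-free neural speech decoding: model, training, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twspeech)
```

## The problem

Intracranial speech decoding predicts the spectrogram of spoken words from
simultaneously recorded cortical activity. Most decoder architectures assume
electrodes arranged on a regular 2D grid (an ECoG array), which excludes
strip and depth (sEEG) electrodes and makes models untransferable across
participants, whose implants never coincide. `twspeech` implements a decoder
that represents each electrode purely by its anatomy — its MNI coordinates
and the brain region it sits in — so any electrode configuration can be
decoded, and one shared decoder can be trained across participants and
applied to participants never seen in training.

## The two-step pipeline

**Step 1 (speech to speech).** A speech encoder maps each spectrogram frame
to 18 interpretable speech parameters — pitch `f0`, six formant frequencies
`f1..f6` with amplitudes `a1..a6`, an unvoiced filter (`fu`, `bu`, `au`),
a voicing mix `alpha`, and loudness `L` — and a differentiable synthesizer
maps the parameters back to a spectrogram. Both are fit by auto-encoding
(`train_speech_autoencoder()`), minimizing the multi-scale spectral loss.

**Step 2 (neural to speech).** The neural decoder (`train_subject()`,
`train_multisubject()`) predicts the same 18 parameters per frame from the
high-gamma feature array; its predictions go through the fixed synthesizer
to produce a decoded spectrogram. Training minimizes

L = L_MSS + 1.2 L_STOI + 0.1 L_supervision + 1.0 L_reference,

where `L_MSS` compares predicted and true spectrograms (mean absolute
magnitude and log-magnitude differences, linear and mel scales),
`L_STOI` is the negative of the STOI+ intelligibility index computed on a
differentiable path, `L_supervision` penalizes pitch/formant-track errors
against an external reference (a Praat-style tracker in clinical use; the
generator's true trajectories in the synthetic pipeline), and
`L_reference` is the per-parameter weighted squared distance to the speech
encoder's parameters. Adam is used with learning rate 5e-4
(beta1 0.9, beta2 0.999) as the reference setting; scaled-down experiments
in this package use larger rates (up to 5e-3), which converge faster at toy
problem sizes.

### Numerical balance of the objective

The 18 parameters live on wildly different scales (Hz vs. unitless). The
standalone loss functions follow their printed definitions exactly
(`supervision_loss()` is in Hz², `reference_loss()` defaults to unit
per-parameter weights). Inside the training loop, the per-parameter
reference weights default to `1/range²` — the "individual weight per
parameter" knob the objective exposes — and the supervision term is computed
on range-normalized tracks, so no single parameter family dominates the
gradient. Both normalizations are configurable (`train_config()`,
`loss_weights()`).

## The decoder architecture

The input is a `T x N` array (frames x electrodes) of high-gamma features.

1. **Temporal patching.** Each electrode's sequence is cut into `T/W`
   patches of `W` frames (default 4); a shared linear embedding produces
   `(T/W) x N` tokens of width `C` (reference value 96).
2. **Temporal-window attention.** Attention is restricted to `Wt` (default
   4) consecutive temporal slots but spans *all* electrodes, i.e. each
   window holds `Wt x N` tokens. Every second layer the partition is
   cyclically shifted by `Wt/2` so information crosses window boundaries.
   Query-key similarity is scaled cosine `cos(q, k)/tau + B_ij` with a
   learnable per-head, per-layer temperature `tau` (softplus-parameterized,
   floored at 0.01, initialized at 0.1).
3. **Anatomical positional bias.** `B_ij` is the sum of (a) a 2-layer MLP
   (hidden width 32, LeakyReLU) on the 12-vector
   `(x_i, y_i, z_i, t_i, x_j, y_j, z_j, t_j, x_i - x_j, y_i - y_j, z_i - z_j,
   t_i - t_j)` — MNI coordinates in units of 100 mm and the temporal slot
   scaled to (0, 1) for conditioning — and (b) the dot product `r_i . r_j`
   of learnable region embeddings (dimension `C_r = 16` per head), indexed
   by the electrode's atlas region. Left- and right-hemisphere regions
   occupy disjoint index ranges, so their embedding dictionaries are
   hemisphere-specific; a shared `Unknown` region (index 0) holds
   electrodes whose location is unknown, which are kept with MNI (0,0,0)
   rather than discarded. The bias MLP is per-layer (matching the per-layer
   temperature); its final layer starts at zero so training begins
   bias-free. Region dictionaries are per-stage (the head count is fixed
   within a stage).
4. **Stages and merging.** Three stages of 2, 2 and 6 transformer layers
   with 3, 6 and 12 heads. After stages 1 and 2, consecutive temporal token
   pairs of each electrode are concatenated (2C) and linearly mapped,
   halving the temporal token count and doubling the latent width — the
   schedule is `(T/W, C) -> (T/2W, 2C) -> (T/4W, 4C)`.
5. **Head.** An MLP (384 -> 196 -> 96 -> 32 at the reference width, with
   layer norm and LeakyReLU between layers) reduces `4C` to `C' = 32`;
   element-wise max pooling over electrodes removes the electrode axis;
   four transposed temporal convolutions (stride 2, kernel 3, padding 1,
   output padding 1) upsample `T/4W` back to `T` — consistent only when
   `4W` is a power of two, which the configuration validator enforces —
   and two temporal convolutions (kernel 3) plus a per-frame MLP emit the
   18 parameters. Outputs are bounded onto the physiological ranges by
   sigmoid scaling, so decoded parameters are always valid.

Transformer blocks use the residual post-norm convention (`x + LN(f(x))`).
Weight initialization is truncated normal with fan-in scaling
(`sd = sqrt(2/fan_in)`): a fixed small standard deviation, conventional for
pre-normalized transformers, attenuates the signal to numerical noise
through this architecture's un-normalized upsampling head, leaving the
output effectively constant at initialization, so fan-in scaling is used
throughout.

### Exact permutation invariance

The decoder's output must not depend on the order in which electrodes are
listed. Attention and max pooling are order-free mathematically, but
floating-point summation is not associative, so a naive implementation is
only invariant up to rounding. `decode_forward()` therefore sorts electrodes
into a canonical order (by id) internally, making the output *bit-identical*
under any joint permutation of features and layout.

## Preprocessing

`extract_high_gamma()` band-passes 70-150 Hz (4th-order Butterworth, applied
forward and backward for zero phase), takes the analytic-signal magnitude as
the envelope, anti-alias filters, resamples to the frame rate (default 125
Hz — a configurable engineering choice), and z-scores each electrode.
`savgol_smooth()` applies the Savitzky-Golay filter (order 3, window 11)
along frames. Artifact-contaminated electrodes arrive as all-zero columns
and stay that way. `select_active_electrodes()` thresholds the pooled
standard deviation, with an explicit threshold argument replacing the
clinical per-subject calibration procedure. `shuffle_control()` provides the
chance-level control: a seeded temporal permutation applied identically to
all electrodes, which destroys the stimulus-locked temporal structure while
preserving every marginal statistic.

## The synthesizer stand-in

The synthesizer is a fixed differentiable source-filter map:

S(t, f) = L_t [ alpha_t * sum_i a_{i,t} G(f; f_{i,t}, b_i) H(f; f0_t)
          + (1 - alpha_t) a_{u,t} G(f; f_{u,t}, b_{u,t}) ]

with `G` a unit-peak Gaussian bump in log-frequency (sigma = b/(2 fc);
formant bandwidths fixed at 80..280 Hz), and `H` an optional soft harmonic
comb at multiples of `f0` (default off; its exact form in production
synthesizers varies, and tests run without it). Spectrograms are 128 linear
magnitude bins up to 8 kHz. The synthesizer has no trainable weights, so
"training the synthesizer" reduces to fitting the encoder; per-participant
synthesizers in the clinical pipeline correspond here to one shared
parametric map. The encoder reads standardized log magnitudes and bounds its
outputs by sigmoid scaling onto the parameter ranges; the staggered formant
ranges (f1 200-1000 Hz, f2 500-2500 Hz, ...) make the formant slots
identifiable during auto-encoding.

## Evaluation metrics

* **PCC** — Pearson correlation between decoded and true spectrograms over
  all time-frequency bins of a trial, averaged per participant over test
  trials (per-trial-then-average, matching the per-trial test protocol).
* **STOI+** — one-third-octave band envelopes (15 bands from 150 Hz),
  correlations of per-segment normalized envelopes (30-frame segments),
  averaged without clipping; range [-1, 1]. Computed natively on
  spectrograms at the package's frame rate.
* **MCD** — `(10/ln 10) sqrt(sum_{0<d<25} (mc_d - mc'_d)^2)` per frame,
  averaged. The text around the printed formula speaks of 25 features while
  the summation bounds cover d = 1..24; the package implements the printed
  bounds (24 coefficients, c0 excluded) and computes mel cepstra as
  mel filterbank -> log -> DCT-II (25 coefficients kept). Absolute MCD
  values depend on the spectrogram convention and are comparable within,
  not across, pipelines.

## Synthetic participants

The generator builds complete participants so the whole pipeline is testable
without patient data:

* **Layouts** (`gen_layout()`): an exact 10 mm 8x8 grid on a lateral MNI
  plane; optional strips, depths and 1-11 unknown-location electrodes; or
  sEEG-only shafts with 19-178 contacts. Regions are assigned by proximity
  to atlas centroids. The shipped atlas is a 12-regions-per-hemisphere
  perisylvian list; region granularity is data, not code, and any atlas
  file with the same format can be substituted.
* **Trajectories** (`gen_speech_trajectories()`): per-word smooth random
  splines inside the physiological ranges; trial realizations add smooth
  jitter (4% of each range), so same-word trials resemble each other more
  than different-word trials. A session holds 8 trials per word across the
  five production tasks (400 trials at the full 50-word inventory), split
  350/50 with 10 test trials per task.
* **Neural forward map** (`make_forward_map()`, `gen_neural()`): each
  parameter gets two cortical source points; electrode weights decay as a
  Gaussian of distance (sigma 20 mm); each parameter trajectory is
  convolved with a random length-5 kernel (neural lead/lag) before spatial
  mixing; Gaussian noise sets the SNR; features are z-scored per
  electrode. For a single subject, sources are sampled within that
  subject's electrode patch. For multi-subject cohorts,
  `population_code()` fixes the sources once per cohort near atlas region
  centroids (with x-mirrored twins, a bilateral representation) and shares
  the temporal kernels, so all subjects sample the *same* neural
  organization through different electrodes — the structure that makes a
  shared anatomy-aware decoder transferable to unseen subjects, and
  without which cross-subject transfer would be impossible by
  construction. The map is exported with the session, so tests measure
  recovery against known ground truth. A ridge-regression baseline from
  lagged features confirms the map is information-preserving (recovery
  correlation > 0.6 at 10 dB SNR), so decoder-recovery tests are feasible
  rather than vacuous.

What the generator does **not** emulate: acoustic realism (no phonetics, no
lexicon), epileptiform artifacts, non-stationary noise, electrode drift, or
any nonlinearity in the neural-to-speech map. Passing recovery tests shows
the architecture and training machinery can invert a known map of realistic
geometry and scale — not that clinical decoding accuracy is reproduced.

## Scaled-down experiment design

All trainable experiments in the tests and the acceptance script run on one
CPU, so problem sizes are scaled down as the package's own choice of study
conditions: decoders use the reference architecture with a narrower latent
(`C = 32`, `C' = 32`, heads 2/4/8, block-MLP ratio 2), subjects have 16
electrodes and 64-frame trials at noiseless SNR, and sessions cover 8 words
(64 trials). The speech-to-speech step is validated on its own
(auto-encoding reconstruction and formant recovery on held-out synthetic
speech). The decoder-recovery and multi-subject experiments supervise the
reference loss with the generator's true parameter trajectories
(`reference = "oracle"`) — the quantity the speech encoder is trained to
approximate — which isolates the decoder mechanism under test from encoder
variance and keeps each experiment's runtime in minutes; passing a trained
`speech_model` runs the same experiments through the full two-step
pipeline. The multi-subject parity experiment trains two subject-specific
decoders and one shared decoder on both subjects (one left-, one
right-hemisphere), then applies the shared decoder unchanged to a third,
unseen synthetic subject and compares it against its shuffled-input
control.

## Numerical choices and degenerate inputs

* Autodiff: the package carries its own reverse-mode engine on dense
  matrices (R/autograd.R) with a fused windowed-attention operation; all
  gradients are validated against finite differences and attention against
  a dense masked oracle.
* Cosine attention epsilon 1e-6; softmax stabilized by max subtraction;
  layer-norm epsilon 1e-5; spectral-loss log epsilon 1e-5; STOI
  normalizations in the loss path carry 1e-8 guards, while the metric path
  is exact and excludes constant band/segment pairs (they carry no
  intelligibility information).
* Max pooling breaks ties to the first maximal electrode (deterministic).
* All randomness flows through explicit seeds; every training run is
  bit-reproducible given its configuration.
* Degenerate inputs: zero-variance inputs to `pcc()` error (undefined);
  all-zero electrode columns are preserved; sessions shorter than 400
  trials split proportionally with a warning; non-finite losses abort
  training with the last good epoch restored.

## Known limitations

* The synthesizer and encoder are stand-ins with stated forms; they
  preserve the 18-parameter semantics and differentiability but do not
  reproduce any particular production voice model.
* STOI+ and MCD are computed from spectrogram frames, not waveforms; their
  absolute scales differ from waveform-based implementations.
* Pure-R training is practical at the scaled-down sizes above (minutes per
  model), not at clinical cohort scale.
* The attention cost grows quadratically in electrode count within each
  temporal window; very dense implants (hundreds of electrodes) would need
  batching adjustments.
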