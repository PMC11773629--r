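# twspeech

Grid-free transformer decoding of speech from intracranial electrodes.

## The problem

Speech neuroprostheses decode intended speech from cortical recordings.
Most published decoder architectures require electrodes on a regular 2D
grid (an ECoG array) and must be retrained per patient, because both their
convolutions and their positional encodings are tied to grid indices. That
excludes strip and depth (sEEG) electrodes — the more common clinical
implant — and blocks training across patients, whose electrode placements
never match.

`twspeech` implements a temporal-window transformer decoder that replaces
grid indices with each electrode's anatomy: attention between two tokens
receives a bias

SIM(q_i, k_j) = cos(q_i, k_j) / τ + B_ij,
B_ij = MLP(x_i, y_i, z_i, t_i, x_j, y_j, z_j, t_j,
           x_i−x_j, y_i−y_j, z_i−z_j, t_i−t_j) + r_i · r_j

where (x, y, z) are MNI coordinates in mm, t is the temporal token index,
and r_i is a learnable embedding of the electrode's brain region
(hemisphere-specific dictionaries; a reserved Unknown region for
unlocalized electrodes). Windowing applies only along time (window Wt = 4,
shifted every other layer); attention always spans all electrodes. Three
stages (2/2/6 layers, 3/6/12 heads) with temporal patch merging compress
T frames to T/16 tokens of width 4C; an MLP, electrode-wise max pooling,
four stride-2 transposed convolutions and a convolutional head emit 18
speech parameters (pitch f0, formants f1–f6 with amplitudes a1–a6, an
unvoiced filter fu/bu/au, voicing mix α, loudness L) per frame. A
differentiable source-filter synthesizer converts parameter trajectories to
spectrograms, so the decoder trains end-to-end against the composite loss

L = L_MSS + 1.2·L_STOI + 0.1·L_supervision + 1.0·L_reference  (Adam, lr 5e-4).

Because no parameter is indexed by subject or grid, one decoder can be
trained on many participants jointly and applied to participants never seen
during training. The package ships the full pipeline: high-gamma
preprocessing, the speech encoder/synthesizer auto-encoding step, the
decoder, all losses, evaluation metrics (spectrogram PCC, STOI+,
mel-cepstral distortion), subject-specific / multi-subject / leave-fold-out
training, and a synthetic-participant generator with a known
neural-to-speech forward map so everything is verifiable without patient
data.

## Worked example

The snippet below is the same experiment `scripts/acceptance.R --seed 1`
runs; the printed numbers are that run's output.

```r
library(twspeech)

# a synthetic participant: 16 depth electrodes, 8 words x 8 trials each
lay <- gen_layout("seeg_only", "left", seed = 3, n_electrodes = 16)
inv <- gen_speech_trajectories(words = sprintf("w%02d", 1:8), T = 64, seed = 2)
ses <- make_split(gen_session(lay, inv, snr = Inf, seed = 4), seed = 6)
#> Warning: session has 64 trials (not 400); using proportional test counts

cfg <- train_config(epochs = 60, batch = 8, lr = 3e-3, seed = 5,
                    reference = "oracle",
                    decoder = decoder_config(C = 48, C_out = 32,
                                             stage_heads = c(3, 6, 12),
                                             mlp_ratio = 2, C_r = 8,
                                             bias_hidden = 16))
fit <- train_subject(ses, NULL, cfg)   # ~10 min on one CPU
evaluate_session(fit, ses)
#> # A tibble: 1 × 5
#>   participant_id   pcc stoi_plus   mcd n_trials
#>   <chr>          <dbl>     <dbl> <dbl>    <int>
#> 1 sim3           0.718     0.666  45.0        8
evaluate_session(fit, ses, shuffle = TRUE, shuffle_seed = 7)$pcc
#> [1] 0.2500158
```

The decoder reconstructs this subject's held-out spectrograms at PCC 0.72
from neural features alone and collapses to 0.25 when the test inputs are
temporally shuffled — the chance-level control. (Held-out PCC varies from
subject to subject with the random electrode placement relative to the
simulated sources: 0.72 here, 0.86 for the subject in
`tests/testthat/test-acceptance.R`.) `reference = "oracle"` supervises with the generator's true
parameter trajectories; passing a `speech_model` from
`train_speech_autoencoder()` instead runs the full two-step pipeline. MCD
values are on this package's spectrogram scale; they are comparable
within, not across, pipelines.

`vignettes/decoding-methods.Rmd` documents the model, the loss balance, the
synthetic forward map, and every numerical choice. A thin CLI over the same
functions lives at `inst/cli/twspeech.R`
(`simulate` / `train` / `decode` / `evaluate`).

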