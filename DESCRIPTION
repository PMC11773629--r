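Package: twspeech
Title: Grid-Free Transformer Decoding of Speech from Intracranial Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes speech from intracranial neural recordings (ECoG grids,
    strips, depth and sEEG electrodes) with a temporal-window transformer that
    represents each electrode by its anatomical position (MNI coordinates and
    brain-region index) instead of a 2D grid index. Implements the two-step
    decoding pipeline: a speech encoder and differentiable formant synthesizer
    trained by spectrogram auto-encoding, and a neural decoder trained to
    predict 18 per-frame speech parameters under a composite spectral,
    intelligibility, supervision and reference loss. Includes high-gamma
    preprocessing, evaluation metrics (spectrogram correlation, STOI+,
    mel-cepstral distortion), subject-specific and multi-subject training with
    hemisphere-specific region embeddings, and a synthetic-participant
    generator with a known neural-to-speech forward map for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
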