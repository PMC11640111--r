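Package: iftcollar
Title: Multi-Rate Smart-Collar Sensor Analysis for Guide Dog Evaluation Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-rate smart-collar sensor recordings
    taken during scripted guide-dog evaluation ("In-For-Training") sessions. The
    package generates labelled synthetic collar sessions (100 Hz inertial, audio
    level and ambient light channels; 1 Hz temperature, humidity and pressure),
    preprocesses them into fixed-shape dataset variants (linear interpolation onto
    a 500-sample grid, 25-sample windowing, per-modality Z-normalisation, sensor
    fusion and state-space selection), classifies behavioural states with a
    convolutional LSTM and with kernel PCA followed by a ridge classifier, and
    builds an unsupervised behaviour lexicon from a convolutional autoencoder via
    latent-density peaks and decoder pre-images. Evaluation utilities include
    confusion matrices, macro-averaged metrics, state-flow (Sankey) mapping with a
    null-state rule and an experiment grid over sampling, state-count and fusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    jsonlite
Suggests:
    kernlab,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
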