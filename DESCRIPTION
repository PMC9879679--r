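Package: saetm
Title: Stacked Autoencoder Topographic Maps for Emotional EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compresses ten linear and nonlinear per-channel EEG features
    (Welch band powers, moments, zero-crossing rate, Higuchi fractal
    dimension, approximate entropy, correlation dimension) into one
    abstracted scalar per channel using per-channel stacked autoencoders
    whose hidden-layer widths are chosen by a correlation-based structural
    loss.  Models are fine-tuned against binary valence/arousal labels and
    the 32 channel scalars are rendered as a single interpolated
    topographic scalp map.  Includes a synthetic generator for
    DEAP-structured emotional EEG with planted band-power and hemispheric
    asymmetry effects, and a small convolutional classifier that scores
    how distinguishable map classes are.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
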