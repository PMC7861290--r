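Package: accdist
Title: Acoustic Pronunciation Distance from Speaker-Normalized Cepstral
    Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes an acoustic-only pronunciation distance between
    speakers reading a common word list. Word-segmented recordings are
    represented as 39-dimensional mel-frequency cepstral coefficient
    (MFCC) features, standardized per speaker with cepstral mean and
    variance normalization (CMVN), and compared word by word with
    length-normalized dynamic time warping (DTW); per-word distances
    are averaged over a native reference set to yield one accent-strength
    score per speaker. Includes the validation statistics used to relate
    such distances to human native-likeness ratings (Pearson and Spearman
    correlation, multiple regression, Steiger's test for dependent
    correlations, Bark-scaled formant distances, classical
    multidimensional scaling) and a deterministic source-filter speech
    synthesizer so every stage is testable without external recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
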