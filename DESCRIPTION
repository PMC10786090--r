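Package: phonrsa
Title: Representational Similarity Analysis of Phonological Prediction in Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing pre-stimulus (predictive) phonological
    similarity coding in event-related EEG with representational similarity
    analysis (RSA). Supports set-structured stimulus designs in which item
    pairs either share a syllable (within-pairs) or do not (between-pairs):
    pair enumeration and pinyin syllable-component similarity, epoch-level
    preprocessing (baseline correction, amplitude-based trial rejection),
    spatial RSA (per-timepoint channel-pattern correlations with a
    predictive-window test, time-cluster permutation using a summed-t mass
    statistic, and a matched-subsample control), temporal RSA (per-electrode
    time-series correlations with an electrode-adjacency cluster-size
    permutation test), a two-stage summary-statistics regression relating
    neural similarity to stimulus similarity covariates, and a synthetic-EEG
    generator with known representational ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
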