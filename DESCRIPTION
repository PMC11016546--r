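Package: ssvepr
Title: SSVEP Decoding with a Multi-Subband Attention CNN and Classical Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency recognition for steady-state visual evoked potential (SSVEP)
    brain-computer interfaces. Implements a four-branch convolutional network in which
    each branch processes one Butterworth subband (7-16, 15-31, 23-46 and 7-50 Hz) of a
    multichannel EEG epoch and is refined by a convolutional block attention module
    (channel attention followed by spatial attention); branch features are fused,
    refined by a second attention block, and classified with a softmax head trained by
    Adam on the cross-entropy loss. Also provides the classical comparison methods
    (canonical correlation analysis, filter-bank CCA, and CCA-feature classifiers with
    a linear support vector machine or Gaussian naive Bayes), an evaluation harness
    (accuracy, per-class precision and recall, macro-F1, information transfer rate,
    paired significance tests), EDF reading and epoching, and a synthetic SSVEP
    generator emulating a 7-lead occipito-parietal montage so the full pipeline runs
    without any EEG download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
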