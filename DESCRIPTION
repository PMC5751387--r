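Package: adaptref
Title: Adaptive Similarity-Based Spatial Referencing for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive variants of the Local Average Reference (LAR) and
    Weighted Average Reference (WAR) spatial filters for multichannel EEG.
    Neighbor electrodes are selected per sample from a sliding-window
    concordance correlation coefficient and an adaptive amplitude-dispersion
    threshold; selected neighbors are weighted by a virtual distance
    exp(-w1 * ccc) so that electrodes carrying neural information similar to
    the target contribute least to the common-interference estimate, and an
    amplitude-correction stage suppresses high-amplitude single-electrode
    artifacts.  The package also provides the surrounding tooling: SSVEP
    signal-to-noise, attenuation and coherence metrics, a 12-feature
    time/frequency feature bank (including Higuchi and Sevcik fractal
    dimensions and seven band powers), unsupervised feature selection by
    representation entropy and the maximal information compression index,
    composite classifier model-selection indices, CCA-based SSVEP frequency
    recognition, recognition-latency analysis, and seeded synthetic EEG
    generators for SSVEP-like and gait-planning-like records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
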