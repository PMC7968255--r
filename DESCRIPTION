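Package: cochleamod
Title: Attentional Modulation Analysis of Ongoing Otoacoustic Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ongoing otoacoustic activity (OOA) recorded
    in the sealed ear canal during silent attention-cueing intervals. Implements
    the full signal path from raw two-ear microphone recordings to group-level
    inference: 500 Hz high-pass filtering, epoching with automated saturation
    rejection, a 1000-2000 Hz bandpass filter bank with Hilbert envelope
    extraction, induced and evoked envelope modulation spectra (1-30 Hz),
    periodic/aperiodic spectral parameterization with Gaussian peak models and
    Dixon's Q peak-significance testing, the attention modulation index (AMI)
    with pooling and one-tailed group tests, circular and uniformity statistics,
    repeated-measures ANOVAs, and cluster-based permutation inference on
    voxel-by-frequency source-power maps for condition contrasts and
    across-subject brain-cochlea correlations. A seeded synthetic-data module
    generates ear-canal recordings, behavioral tables, and source-space power
    grids with known planted structure so the entire pipeline is testable
    without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
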