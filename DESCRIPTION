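Package: flimAdapt
Title: Adaptive Intensity-Inverted Exposure Planning and TCSPC Simulation for FLIM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual microscope for adaptive fluorescence lifetime
    imaging (FLIM). Simulates time-correlated single-photon counting (TCSPC)
    acquisition of synthetic heterogeneous samples under arbitrary per-pixel
    dwell-time maps, plans adaptive exposure maps by intensity inversion of a
    pre-scan (dark-count and adaptive Otsu pixel classification, photon-target
    inversion with caps and quantization), synthesizes galvanometer scan
    waveforms with settling insertion, smoothing and embedded clocks, estimates
    per-pixel lifetimes by the centre-of-mass method and by least-squares decay
    fitting, and evaluates adaptive against uniform-exposure imaging in
    equal-time (signal enhancement) and equal-SNR (speedup) modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    withr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'phantom.R'
    'tcspc.R'
    'planner.R'
    'waveform.R'
    'lifetime.R'
    'evaluation.R'
    'io.R'
    'cli.R'
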