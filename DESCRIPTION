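Package: neurocult
Title: Quantification of Viability, Neurite Outgrowth and Calcium Activity
    in Low-Density Neuronal Culture Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-quantification pipeline for astrocyte-neuron co-culture
    experiments. Counts live and dead cells from multi-channel fluorescence
    micrographs by robust semi-automatic thresholding, measures total neurite
    length by skeletonization, detects calcium transients in GCaMP-type
    recordings with a Mexican-hat continuous wavelet transform, and compares
    co-culture against control conditions with replicate-aware nonparametric
    statistics (exact one-sided Mann-Whitney U, IQR outlier exclusion,
    per-biological-replicate fold changes). Includes a synthetic-data
    generator that emulates the full multi-well experiment with known ground
    truth (cell positions, polyline neurite lengths, Poisson spike trains)
    for end-to-end validation of every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
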