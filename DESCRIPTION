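Package: calcitrace
Title: Stimulus-Evoked Calcium Transient Analysis and Immunofluorescence
    Cell Classification for Cultured Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of stimulus-evoked cytoplasmic calcium
    transients in cultured neurons imaged with a fast fluorescence camera:
    dark-frame background subtraction, pre-stimulus baseline (F0) estimation,
    dF/F0 conversion, dendritic region-of-interest and single-pixel trace
    extraction, RMS-thresholded peak detection, single-exponential decay
    fitting with goodness-of-fit rejection, cumulative calcium load over
    stimulus trains, and subcellular spatial gradient profiling. Also
    classifies immunostained cells as marker-positive or -negative using the
    upper limit of a 95% simultaneous (Working-Hotelling-Scheffe) confidence
    band fitted to negative-control intensity versus log10 somatic area, and
    summarizes cell-type proportions. A seeded synthetic-data generator
    produces fluorescence image stacks and immunostaining populations with
    known ground truth so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
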