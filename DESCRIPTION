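Package: ms2burst
Title: Transcriptional Bursting Inference from MS2/MCP Live-Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of nascent transcription measured
    live with the MS2/MCP reporter system. The package processes per-nucleus
    fluorescence traces (gap interpolation, active-period segmentation,
    onset alignment), calibrates arbitrary-unit MS2 intensities to absolute
    nascent-mRNA counts against smFISH spot intensities via quantile-quantile
    matching, deconvolves calibrated traces into discrete RNA polymerase II
    initiation events, fits multi-exponential survival models to
    inter-initiation waiting times to select the number of promoter states and
    invert them into the rates of a nonsequential three-state bursting model,
    and quantifies coactivator hub enrichment and hub-transcription
    cross-correlation. A synthetic-data module generates every input the
    pipeline consumes, with known ground truth, from an exact stochastic
    simulation of the promoter state chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
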