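Package: peakfreq
Title: Peak-Frequency Annotation of Intracardiac Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wavelet-based peak-frequency annotation of intracardiac
    electrograms for discriminating near-field from far-field activity
    around pulmonary-vein ablation lines. Computes continuous-wavelet
    scalograms and per-sample peak-frequency traces, derives bipolar and
    omnipolar electrograms from grid-catheter electrode cliques, applies
    voltage and peak-frequency threshold criteria to call conduction gaps
    versus blocks, and evaluates criteria with ROC/Youden cutoff
    optimisation and contingency-table diagnostics. Includes a synthetic
    electrogram simulator producing labelled gap/block mapping sites for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
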