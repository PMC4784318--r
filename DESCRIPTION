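Package: sortseqtools
Title: Simulation and Inference for Sort-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the design and analysis of sort-seq (FACS-seq)
    experiments, in which a library of genetic variants is sorted into
    fluorescence gates and sequenced per gate. Simulates binned
    fluorescence data under log-normal input distributions for single- and
    dual-reporter designs; estimates per-variant mean and cell-to-cell
    variability with simple moment estimators and (censored,
    outlier-robust) maximum-likelihood estimators; benchmarks estimator
    bias and efficiency across gate configurations; regroups gates and
    normalizes read depth for reanalysis of published gate-fraction data;
    fits additive and pairwise-interaction sequence-activity models by
    nonlinear least squares and by mutual-information maximization; and
    computes enrichment-based epistasis statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
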