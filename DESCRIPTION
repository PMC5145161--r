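Package: blocksort
Title: Block-Wise Superparamagnetic Spike Sorting for Long Noisy
    Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised spike sorting for long, noisy extracellular
    micro-electrode recordings. Detects and extracts action potentials,
    removes artifact events with rule-based criteria before and after
    sorting, clusters spikes block-wise with superparamagnetic (Potts
    model) clustering over a temperature sweep, selects clusters at
    multiple temperatures, assigns residual spikes by two-stage template
    matching, flags non-neural clusters, and merges clusters within and
    across blocks so that single units can be tracked over many hours.
    Includes a ground-truth recording simulator (template neurons,
    background noise, multi-unit hash, artifacts, amplitude drift) and
    evaluation tools: hit scoring against ground truth and a
    stimulus-response score for screening experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    parallel,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
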