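Package: dendricap
Title: Dendritic Excitability Analysis for Purkinje Neuron Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of Purkinje neuron dendritic excitability
    from whole-cell patch-clamp data. Decomposes voltage-clamp capacitative
    transients into a two-compartment equivalent circuit (somatic and distal
    dendritic capacitances and access/coupling resistances) via biexponential
    fitting; extracts spike features (dV/dt-based threshold, half-width,
    peak-to-antipeak amplitude) from current-clamp traces; models
    distance-dependent attenuation of back-propagating action potentials with
    single-exponent fits, length constants, and extra sum-of-squares F tests
    comparing pooled versus per-group curves; determines dendritic calcium
    spike current thresholds with windowed input-resistance estimation and
    cell-usability rules; and screens ion-channel gene expression tables
    against the IUPHAR voltage-gated channel classification. A seeded
    synthetic-data generator reproduces the statistical structure of every
    input so the full pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
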