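Package: qmarkereval
Title: Quality-Marker Discovery and Quality Evaluation for Herbal HPLC Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end chemometrics toolkit for quality-marker (Q-marker)
    work on multi-batch herbal material, built around a 44-batch Gentiana
    scabra Bunge. case study. Covers HPLC fingerprint construction (peak
    detection, retention-time calibration, common-peak matching at a fixed
    time window, median reference chromatogram, cosine similarity, RSD
    method-validation statistics), marker screening by correlation-matrix PCA
    and OPLS-DA with VIP > 1 selection, a fluorescence-quenching
    activity-percentage statistic with Z-score ranking for small
    molecule-protein interaction screening, linear calibration-curve
    quantification with spike recovery, and a quality-ranking stage combining
    a first-principal-component composite score, entropy-weighted TOPSIS
    closeness, and hierarchical cluster grading. Ships the published 44-batch
    content table as a plain-text fixture and a synthetic-data generator for
    chromatograms, fluorescence plates and content tables so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
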