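Package: pulsefit
Title: Pulse-Labeling Proteome Turnover Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic SILAC (pulse-labeling) proteome turnover
    analysis in bacteria: per-protein replacement times, disappearance and
    production rates, and half-life based classification of proteins as
    diluted by growth, actively degraded, or production-stagnated, with
    MAD-based outlier handling and model-quality gates. Includes a
    ground-truth synthetic data generator for pulse-labeling experiments,
    a lysine-unique search-database builder that concatenates lysine-free
    tryptic peptides into artificial proteins, steady-state differential
    proteome analysis (acceptance filtering, downshifted-normal imputation,
    fold-change calls, relative-iBAQ class fractions vs growth rate), and
    physiology utilities (windowed log-OD growth-rate estimation,
    fermentation-profile and arginine-deiminase proxies from relative NMR
    peak intensities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
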