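Package: silkhet
Title: Heterotic Pattern Analysis of 2-DE Proteomic Spot Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for replicate-level two-dimensional gel
    electrophoresis (2-DE) spot densitometry in parent/F1-hybrid designs,
    as used in proteomic studies of heterosis. Implements total-quantity
    parts-per-million normalization of per-gel spot intensities,
    differential-accumulation screening (replicate same-trend rule,
    one-way ANOVA, maximum fold-change filters), six-category heterotic
    pattern classification of F1 protein accumulation relative to the
    mid-parent, high-parent and low-parent values, mid-parent heterosis
    statistics and Fisher LSD letter groupings for seed-setting-rate
    phenotypes, and a synthetic-data generator with truth labels for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
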