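Package: stressel
Title: Selection on Gene Expression under Single and Combined Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links individual-level transcript abundance to individual-level
    fitness in a full-sib split-family design under control, drought, heat and
    combined heat-drought conditions. Provides TMM/CPM normalization and
    within-condition z-scoring, stand-in differential-expression tests with
    Benjamini-Hochberg control, classification of combined-stress response
    modes against twenty predefined expression profiles, per-gene phenotypic
    selection-gradient estimation on standardized expression with
    cross-environment comparisons and permutation tests for adaptive
    plasticity, family-mean plasticity estimation with indirect selection on
    plasticity, factorial fitness models with family-bootstrap standard
    errors, and a negative-binomial synthetic-data generator emulating the
    split-family study design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
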