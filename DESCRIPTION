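Package: permeatr
Title: In Vitro Permeation Analysis for Franz Diffusion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro permeation tests (IVPT) run in
    Franz diffusion cells: sampling-corrected cumulative permeated amounts
    with withdraw-and-replace aliquot correction, candidate release-kinetics
    fitting (zero-order, first-order, Higuchi) with selection by
    degrees-of-freedom-adjusted R-squared, steady-state flux, permeability
    coefficient and lag-time estimation, and transmucosal water loss (TMWL)
    barrier screening of waterproofing formulations including cross-membrane
    correlation. Includes a generative Fickian membrane model with
    withdraw-and-replace sampling and synthetic TMWL panels so every
    analysis stage can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
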