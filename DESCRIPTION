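Package: condensage
Title: Quantitative Analysis of Biomolecular Condensate Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the liquid-to-solid transition (aging) of
    biomolecular condensates from microscopy and plate-reader data. Implements
    passive particle-tracking microrheology (sub-pixel spot detection,
    trajectory linking, ensemble mean-squared displacement, diffusive exponent
    estimation, generalized Stokes-Einstein viscoelastic moduli, and
    viscous/Maxwell/elastic material-state classification), fluorescence
    recovery after photobleaching (FRAP) analysis (acquisition-bleaching
    correction, normalization, immobile fraction, exponential recovery
    fitting, apparent diffusivity), enzyme kinetics (initial rates,
    Michaelis-Menten fitting, relative reaction rates), thioflavin T
    aggregation kinetics (sigmoid fitting), and condensate image metrics
    (segmentation, cargo enrichment index, condensate counting, line
    profiles). Includes seeded synthetic-data generators for every input
    class, so the full pipeline is testable without raw microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
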