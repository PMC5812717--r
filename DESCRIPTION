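Package: myomech
Title: Diaphragm Muscle Mechanics, Elastography and Respiratory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for passive mechanics and stiffness of
    dystrophic diaphragm muscle. Fits the Veronda-Westman hyperelastic
    model to passive-stretch recordings to estimate the zero-strain
    Young's modulus and the exponential stiffening rate; estimates
    elastic wave speed from phase-sensitive optical coherence
    elastography (OCE) fields by cross-correlation time-of-flight and
    converts it to Young's modulus with a Rayleigh surface-wave model;
    applies the one-standard-deviation breath-frequency exclusion rule
    to whole-body plethysmography logs; partitions variance in stiffness
    and force across fibrosis and tubulin measures with adjusted R-squared
    regression tables; and quantifies microtubule density from
    fluorescence image stacks by sum-binarize-fraction. A seeded
    synthetic-data module generates every input with recorded ground
    truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    signal,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
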