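Package: aromakey
Title: Key Aroma Compound Identification from GC-O-MS Volatilomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying key aroma compounds from
    multi-group GC-O-MS studies of fermented foods: retention-index based
    identification against an n-alkane ladder, internal-standard
    semi-quantitation, relative odor activity value (rOAV) screening,
    GC-olfactometry consensus detection and the rOAV/GC-O intersection,
    chemical-class aggregation with hierarchical clustering, a from-scratch
    NIPALS chemometrics core (PCA, PLS1/PLS2, OPLS-DA with VIP, permutation
    validation and CV-ANOVA), PLSR against sensory attributes with jack-knife
    coefficient significance, and one-way ANOVA with Fisher-LSD compact letter
    displays. Ships a seeded synthetic-data generator with planted ground
    truth so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
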