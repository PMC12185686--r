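Package: synthonspace
Title: Reaction-Driven Combinatorial Fragment Spaces from Retrosynthetic
    Transform Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Translates LHASA-style CHMTRN/PATRAN retrosynthetic transform
    patterns into reaction SMARTS, filters building-block collections with
    reactant-level KILL rules (ONPATH/OFFPATH masking, GOTO paths and
    cross-reactant sub-reaction splitting), and encodes the resulting
    products as a combinatorial fragment space of typed synthons that
    supports exact product counting, seeded sampled enumeration,
    retro-validation, membership tests and additive-property histograms
    without materializing the product list. Includes a self-contained
    molecular core (SMILES, ring perception, switchable aromaticity
    models, a SMARTS-subset matcher) and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
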