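Package: stalkmech
Title: Biomechanical Phenotyping of Maize Stalk Lodging Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts raw instrument traces from field and laboratory stalk
    strength tests into plant-, organ-, and tissue-level phenotypes for
    stalk lodging research. Parses structured force-rotation CSV files from
    field lodging devices and computes structural bending strength and
    flexural stiffness from the cantilever deflection model; extracts minor
    diameter, rind thickness, rind penetration resistance and an integrated
    puncture score from universal-testing-machine puncture traces; analyses
    long-span and micro three-point-bending tests for structural and tissue
    level stiffness, strength, flexural stress, strain and Young's modulus;
    converts node bounding-box annotations of calibrated stalk images into
    internode lengths; derives linear density and cellulose/hemicellulose
    composition; validates and error-corrects triple-redundant QR plant
    identifiers; and ships a seeded synthetic trace generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
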