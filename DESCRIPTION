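Package: milkscreen
Title: LC-HRMS Multiresidue Screening of Antibiotics in Milk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted screening pipeline for veterinary antibiotic residues in
    bovine, ovine, and goat milk by liquid chromatography coupled to
    high-resolution (Orbitrap) mass spectrometry. Provides exact monoisotopic
    mass and adduct m/z arithmetic over a packaged 57-compound target panel,
    feature-to-compound matching under ppm and retention-time tolerances with
    identification-point scoring, calibration-based semi-quantification with
    cut-off screening verdicts and batch quality control, a seeded synthetic
    instrument-data generator, and the complete screening-validation
    statistics required for official-control methods: threshold value,
    cut-off factor, detection capability (cc-beta), within-laboratory
    precision against Horwitz-style guide values, specificity, calibration
    stability, and ruggedness t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
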