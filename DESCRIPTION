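Package: oximpp
Title: Targeted and Non-Targeted Analysis of Charge-Switch Derivatized
    Oxylipins by Ion Mobility Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Workflow for oxylipin lipidomics after AMPP charge-switch
    derivatization analyzed by drift-tube ion mobility quadrupole
    time-of-flight mass spectrometry. Provides elemental-formula mass
    arithmetic and the AMPP/2H5-AMPP derivatization conventions, a packaged
    52-analyte reference library of derivatized hydroxy, dihydroxy and epoxy
    polyunsaturated fatty acids, single-field drift-time to collision cross
    section calibration, diagnostic-fragment filtering and cross-sample
    consensus matching of molecular features, targeted quantification with
    calibration-limit rules, light/heavy isotope-pair relative
    quantification, and a ground-truthed synthetic feature-set generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
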