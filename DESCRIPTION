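Package: glycotraits
Title: Derived-Trait Analysis of MALDI-TOF N-Glycomics Spectra with SILAC Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composition-centric analysis of MALDI-TOF mass spectra of
    ethyl-esterified, sodiated N-glycans. Provides exact monoisotopic mass
    arithmetic and isotope-pattern computation for glycan compositions,
    combinatorial composition assignment within a ppm tolerance, internal
    recalibration against univocal calibrant glycans, quality-control filtering
    (isotopic fit, signal-to-noise, mass accuracy), total-signal normalization,
    and a derived-trait calculus (glycan type, fucosylation, linkage-specific
    sialylation, hexose/HexNAc ratio, antennarity). Includes a synthetic-spectrum
    generator emulating a replicated two-group cell-line design, replicate
    averaging with PCA/Hotelling T-squared outlier screening and Student t-tests,
    and SILAC heavy:light ratio utilities (isotope incorporation, arginine-to-
    proline interconversion correction, median protein ratios, fold-change
    selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
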