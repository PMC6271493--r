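Package: flavokin
Title: Kinetic and Thermodynamic Models of Flavylium Pigment Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and nonlinear least-squares fitters for the solution
    chemistry of flavylium (3-deoxyanthocyanidin) pigments: multistate
    acid-base/hydration speciation, Fe(III) and Fe(II) binding kinetics and
    equilibria observed by UV-visible spectroscopy, serum-albumin binding by
    inner-filter-corrected fluorescence quenching, and inhibition of
    heme-induced lipid peroxidation followed as conjugated-diene
    accumulation. Includes a synthetic-data generator with known ground
    truth so every fitter can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
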