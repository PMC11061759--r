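Package: spherorheo
Title: Broadband Viscoelastic Moduli of Multicellular Spheroids from
    Coverslip Compression Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for rheo-optical compression assays of
    multicellular spheroids. A submerged glass coverslip applies a constant
    net load to a spheroid while time-lapse microscopy records the growing
    diametral cross-section; the package segments the spheroid in each
    frame, converts morphology to stress and strain time series under a
    volume-conserving oblate-spheroid model, and evaluates broadband
    viscoelastic moduli two independent ways: by fitting the four-element
    Burgers model in the time domain and mapping it to the frequency
    domain, and by a model-free Fourier transform of the sampled stress
    and strain records (the i-Rheo route). Includes compressional-to-shear
    conversion, loss tangent, nanoindentation creep ingestion, group
    statistics, a physically consistent synthetic-data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    optparse,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
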