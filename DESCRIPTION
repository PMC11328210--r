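Package: starkir
Title: Electric-Field-Dependent Infrared Difference Nanospectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for bias-dependent photothermal (AFM-IR)
    infrared nanospectra: construction of at-bias minus zero-bias
    difference spectra from interleaved acquisition series, fitting of
    the vibrational Stark effect in the Liptay derivative basis,
    extraction of the vibrational dipole-moment change with
    parallel-plate field calibration, classification of difference
    line shapes (Stark broadening versus molecular reorientation), and
    amide-I difference-feature analysis for membrane-protein spectra.
    Includes a seeded synthetic-data generator emulating the
    acquisition protocol so the full pipeline runs without instrument
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
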