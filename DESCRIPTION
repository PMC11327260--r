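Package: grindcurve
Title: FTIR Grinding-Curve Screening of Tooth Enamel Preservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the infrared grinding-curve method used to screen
    fossil tooth enamel before electron spin resonance / uranium-series
    dating. Computes the two crystallinity statistics of carbonate
    hydroxyapatite from transmission FTIR spectra (the full width at half
    maximum of the nu3 phosphate band near 1034 1/cm and the infrared
    splitting factor of the nu4 doublet at 604 and 565 1/cm), assembles
    repeated-grinding measurements into grinding curves fitted by least
    squares, pools replicate curves into species reference curves, and
    classifies test specimens by the vertical offset of their curve from
    the reference. Includes a registry of African ungulate reference
    species, readers for two-column CSV and JCAMP-DX spectra, a synthetic
    enamel-spectrum generator for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tools
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
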