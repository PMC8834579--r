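Package: nucleoshape
Title: Quantification of Nuclear Shape and Nuclear Envelope Abnormalities in Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-nucleus shape descriptors (form factor, eccentricity, solidity,
    mean negative boundary curvature, elliptic Fourier descriptors, radial and
    point asymmetry) and automated detectors for micronuclei, nuclear envelope
    blebs and nuclear envelope invaginations in 2D multichannel fluorescence
    micrographs (DNA stain plus optional lamin-B/lamin-A/C/whole-cell channels).
    Includes a synthetic micrograph generator that plants nuclei, micronuclei,
    blebs and invaginations with ground truth so every operator can be validated
    against known objects, plus an end-to-end pipeline with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
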