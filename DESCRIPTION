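Package: vlcpufa
Title: VLC-PUFA-Based Quantification of RPE Phagocytosis from LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Targeted lipidomics pipeline for quantifying photoreceptor outer
    segment (POS) phagocytosis by retinal pigment epithelium (RPE) cells from
    very-long-chain polyunsaturated fatty acid (VLC-PUFA) marker species
    measured by negative-mode full-scan LC-MS. Computes theoretical
    deprotonated-ion m/z and fragment ladders for fatty acids, extracts ion
    chromatograms at ppm tolerance, detects and integrates chromatographic
    peaks matched to a retention-time library, normalizes peak areas to an
    internal standard, and derives assay metrics: composition profiles, molar
    amounts per POS and per cell, percent phagocytosis impairment, and
    replicate coefficients of variation. Includes a synthetic LC-MS run
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
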