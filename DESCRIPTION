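Package: hilicraman
Title: Chemometric Unmixing and Quantification for Hyphenated
    Chromatography-Raman Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of two-dimensional spectro-chromatograms recorded by
    coupling liquid chromatography (in particular hydrophilic interaction
    chromatography of sugars) with Raman detection.  The data matrix
    (wavenumber by elution time) is factorized by singular value
    decomposition and rotated onto a library of model component spectra by
    a regular matrix K, resolving analyte spectra and their elution curves.
    Resolved elution curves are quantified by Gaussian peak fitting and
    window integration, calibrated by linear regression with limits of
    detection and quantification, and converted to weight-percent content
    of complex samples against single-compound standards.  A synthetic
    data generator with full ground truth emulates the statistical
    structure of such measurements (sharp solvent bands, spectral channel
    masks, tailing elution peaks, solvent intensity fluctuation, baseline
    dips, band-shift artifacts, detector noise) so that every stage of the
    pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
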