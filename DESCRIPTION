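Package: mitopsi
Title: Mitochondrial Membrane Potential from Multi-Wavelength Heme Absorbance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optical inference of mitochondrial membrane potential (delta-psi-m)
    from multi-wavelength transmission spectroscopy of cytochrome bc1 b hemes.
    Converts raw transmitted-light spectra to absorbance, decomposes the alpha
    band (540-580 nm) into reduced-chromophore amplitudes plus a linear baseline
    by linear least squares, forms the normalized statistic fbL = bL/(bL + bH),
    calibrates fbL against delta-psi-m measured by a TPMP+-selective electrode
    (Nernstian analysis with binding correction), fits the variable-slope
    four-parameter logistic calibration curve with bootstrap confidence bands
    and censored inverse prediction, and runs the full ischemia-reperfusion
    time-series pipeline with signal-to-noise based quality control. Includes
    seed-deterministic synthetic-data generators with aligned ground truth for
    every instrument stream.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
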