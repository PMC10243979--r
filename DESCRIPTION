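Package: xrftag
Title: Lanthanide-Tag Panel Design and Synchronous X-Ray Fluorescence
    Imaging Analysis
Version: 0.1.0
Authors@R:
    person("xrftag", "authors", email = "xrftag@example.org",
           role = c("aut", "cre"))
Description: Tools for planning and analysing synchrotron X-ray
    fluorescence (XRF) imaging experiments that use lanthanide-tagged
    antibodies to detect biological epitopes simultaneously with
    endogenous and exogenous elements.  Includes an embedded X-ray
    emission-line catalogue with a silicon-drift-detector resolution
    model, forward simulation of emission-only XRF spectra,
    peak-convolution analysis for selecting usable lanthanide labels,
    per-pixel non-negative least-squares spectral fitting into elemental
    maps, confocal depth-stack geometry correction and exogenous-particle
    statistics, pixel-level label/cell colocalization statistics, and a
    synthetic tissue-phantom generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
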