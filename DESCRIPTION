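Package: specfilt
Title: Retinally Referenced Metrics for Filters Manipulating Short-Wavelength Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the visual and non-visual consequences of optical
    filters ('blue-blocking' and 'blue-attenuating' tints) from their
    spectral transmittance alone. Implements four retinally referenced
    metrics -- luminous transmittance, melanopsin transmittance, colour
    shift in the CIE 1976 u'v' (10 degree) chromaticity diagram, and
    colour-gamut reduction over a representative reflectance sample set --
    together with an analytic sigmoid cut-off filter simulator, a cleaning
    and resampling pipeline for digitized transmittance curves (PCHIP
    interpolation, edge zero-fill, negative clipping), a light-adapted
    pupil-size and retinal-illuminance model, and batch database analysis
    with category summaries and metric correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
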