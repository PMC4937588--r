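Package: pwvttf
Title: Time-to-Foot Pulse Wave Velocity from Phase-Contrast Flow Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures thoracic aortic pulse wave velocity (PWV) from
    phase-contrast MR flow curves using the time-to-foot transit-time method:
    each curve's systolic foot is located as the intersection of a tangent
    fitted to the maximal upslope with a late-diastolic baseline tangent, and
    PWV is the aortic centre-line distance between the two measurement planes
    divided by the transit time. Includes a synthetic aortic waveform
    generator and a computer-phantom framework for determining the acquired
    temporal resolution required for accurate PWV (known-PWV phantom pairs,
    anti-aliased downsampling, per-frame-count error tables and cut-off
    determination), eddy-current baseline correction, ROI-based flow
    extraction from velocity maps, centre-line travel-distance measurement,
    and Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
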