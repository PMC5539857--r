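Package: qusim
Title: Quantitative Microultrasound Tissue Characterization and
    Focused-Transducer Output Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative microultrasound
    (QUS) characterization of layered gastrointestinal tissue. Generates
    pulse-echo radio-frequency B-scans of layered phantoms with matching
    quartz-flat reference echoes, segments the mucosa/submucosa region of
    interest by dB thresholding, morphological closing and largest-region
    selection, and estimates acoustic impedance, attenuation and backscatter
    coefficient per A-line with attenuation compensation. Also computes the
    acoustic-output metrics of a miniature focused ultrasound transducer
    (electrical input power, electroacoustic efficiency, spatial-average
    intensity, mechanical index, radiation-force-balance power) and analyses
    transepithelial electrical resistance (TER) time series for
    barrier-function response to insonation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
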