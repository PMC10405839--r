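Package: ringtomo
Title: Ring-Array Optoacoustic and Ultrasound Tomography for Fatty-Liver
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction pipeline for hybrid ring-array
    imaging of murine fatty liver disease. Generates digital mouse and
    ex-vivo liver phantoms with cohort-level statistical structure,
    simulates multispectral optoacoustic (MSOT) sinograms and synthetic
    transmit aperture (STA) pulse-echo/transmission records on a circular
    transducer array, reconstructs optoacoustic images by dual
    speed-of-sound back-projection with modified-Bessel fluence
    correction, compounds reflection ultrasound (RUCT) images by
    delay-and-sum, estimates quantitative speed-of-sound maps by
    time-of-flight initialized gradient-descent waveform inversion,
    unmixes hemoglobin, melanin and lipid chromophores, and reproduces
    group-level liver statistics (speed of sound, lipid contrast,
    cross-sectional area) on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    pracma,
    signal,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
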