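Package: nusquant
Title: Non-Uniform Sampling Schedules for Quantitative NOESY NMR
Version: 0.1.0
Authors@R: person("nusquant", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generation and evaluation of non-uniform sampling (NUS) schedules
    for quantitative 2D NOESY NMR. Provides Poisson-gap, random-shuffle and
    uniform-prefix ("US-NUS hybrid") schedule generators on a Nyquist grid with
    Bruker-style nuslist serialization; schedule quality metrics derived from
    the point-spread function (peak-to-sidelobe ratio, relative sensitivity,
    signal apex-to-artefact ratio, forward-weighting fraction); an iterative
    soft-thresholding reconstructor for subsampled interferograms; a synthetic
    NOESY simulator (mixing-time series of diagonal and cross-peak integrals
    with cross-relaxation rates scaling as the inverse sixth power of the
    interproton distance, optionally full 2D time-domain data); PANIC
    normalization, outlier-trimmed linear build-up fitting and interproton
    distance extraction; and uniform-versus-NUS fidelity reports (retained
    distances, deviation-cutoff tables, average deviation, L2 norm).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
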