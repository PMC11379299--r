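Package: vbpbb
Title: Variable Bandpass Periodic Block Bootstrap for Periodically
    Correlated Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for estimating and testing periodic mean components of
    long, regularly sampled environmental time series such as hourly air
    pollutant records.  Implements the Kolmogorov-Zurbenko Fourier
    Transform (KZFT) bandpass filter from its polynomial coefficient
    definition, periodogram screening of candidate frequencies, the
    General Seasonal Block Bootstrap (GSBB), and the Variable Bandpass
    Periodic Block Bootstrap (VBPBB), which bandpass-filters a series to
    isolate one periodically correlated component before phase-preserving
    block resampling.  Produces per-phase percentile confidence bands for
    the periodic mean, a horizontal-line significance criterion, and
    band-width comparison statistics, together with a ground-truth
    synthetic hourly series generator and a reader for EPA AQS
    pre-generated hourly data files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
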