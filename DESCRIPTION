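Package: refcurveB
Title: Continuous Age-Matched Reference Values for Pediatric B Cell Subpopulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds continuous, age-matched reference values for the major
    peripheral-blood B cell subpopulations (naive, non-switched memory and
    switched memory B cells) in children. A three-parameter exponential
    model y = a + b*exp(c*age) is fitted to subset frequencies and absolute
    counts by profiled least squares, and distribution-free reference bands
    at confidence probabilities 0.90 and 0.95 are obtained by shifting the
    fitted curve by empirical residual quantiles. Includes a synthetic
    cohort generator emulating pediatric B cell development, study-style
    inclusion screening, a per-patient reference calculator with abnormality
    flags, a CD19-versus-CD20 denominator comparison, and tools contrasting
    continuous references with conventional age-group percentile tables.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
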