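Package: n3lband
Title: Natural-Log Frequency Band Decomposition for Neuroimaging Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the theoretically fixed natural-log-linear (N3L) frequency
    bands that a recording's sampling parameters can support, decomposes
    multivariate time series (4D NIfTI volumes, parcel-by-time matrices, scalar
    motion traces) into those bands with an FFT bin-masking filter bank, and
    implements two downstream analyses: multi-band framewise-displacement head
    motion statistics (exponential age models, sex contrasts, repeated-measures
    ANOVA) and multi-band amplitude of low-frequency fluctuation (ALFF) with
    test-retest reliability estimated by intraclass correlation from linear
    mixed models. Includes seeded synthetic-data generators for every input
    class, used for parameter-recovery and calibration tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    lme4,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
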