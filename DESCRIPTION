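Package: aviseq
Title: Simulation, Base Calling and Error Profiling for Avidity (Polony) Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational layer for avidity (polony) sequencing data: a
    forward simulator of per-cycle four-channel polony intensities with
    lag/lead phasing, spectral cross-talk, brightness variation and signal
    decay; the primary-analysis base caller that inverts cross-talk and
    phasing, normalizes intensities and calls bases by maximum normalized
    intensity; empirical phred quality-table training from four intensity
    predictors with calibration assessment; fitting of nucleotide
    incorporation and avidite binding kinetics (single-exponential traces,
    hyperbolic concentration dependence, association and dissociation
    rates); and alignment-based error characterization around homopolymers
    and across k-mer contexts against a variant-masked reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    minpack.lm,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
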