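Package: irboundary
Title: Chromatin Boundary Detection at Inverted Repeats from
    Non-Denaturing Bisulfite Footprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping single-stranded DNA exposure on
    chromatinized templates by non-denaturing bisulfite sequencing and
    for locating the chromatin boundary formed at an inverted repeat
    (IR) inside a Ty1-like LTR retrotransposon. Provides a bisulfite
    read simulator with known ground truth, a three-letter bisulfite
    aligner with the multi-mapping and indel read filters used in such
    studies, strand-specific per-base CT conversion-rate profiles, a
    binomial single-changepoint estimator that formalizes the boundary
    ("tipping point") call, inverted-repeat detection with a
    Nussinov-style hairpin folder and in-silico mung-bean-nuclease PCR,
    ChIP metaprofile aggregation over anchored elements, and the
    ChIP-qPCR percent-of-input, transformation-efficiency and
    ACT1-relative expression calculators with their group tests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
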