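Package: clonehier
Title: Reconstruction of Clonal Hierarchies from Bulk Variant Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates all rooted labeled mutation trees (clonal hierarchies)
    compatible with bulk variant-allele-frequency measurements of a leukemia
    sample at one or more timepoints. Trees are enumerated exhaustively via
    Pruefer sequences, mapped to unit-upper-triangular clone-membership
    matrices, and fitted against the measured frequencies by exact
    back-substitution or, for incompatible data, by non-negative least squares
    on the frequency simplex. Includes wild-type-root and relaxation modes for
    samples with multiple founding clones, robustness analyses (multinomial
    resampling of single-cell clone counts, Gaussian perturbation of VAFs,
    exhaustive uniqueness experiments), and a synthetic patient generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
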