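Package: svccf
Title: Cancer Cell Fraction Inference for Structural Variant Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates variant allele frequencies of structural-variant (SV)
    breakpoints from whole-genome alignments, infers each SV's cancer cell
    fraction (CCF) and multiplicity with a dual-breakend Bayesian binomial
    mixture model fitted by variational inference, and clusters SVs into
    clonal and subclonal populations. Includes breakend annotation and SV
    classification, split/spanning/normal read counting with a purity- and
    ploidy-aware correction for DNA-gain events, background copy-number
    assignment from allele-specific segmentations, post-assignment of
    variants to reference cluster fits, clonality statistics (subclonal
    classification, balanced-rearrangement enrichment, a binomial versus
    beta-binomial dispersion test), benchmarking metrics against known
    truth, and a synthetic count-level data generator with in-silico
    two-sample mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
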