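Package: duplexmt
Title: Somatic Mitochondrial DNA Mutation Analysis for Duplex Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a Duplex
    Sequencing analysis of low-frequency somatic mitochondrial DNA
    mutations in aged mouse tissues. Provides a synthetic duplex
    read-family simulator with strand-specific DNA-damage artifacts,
    single-strand and duplex consensus calling (SSCS/DCS), somatic
    variant filtering (masked regions, NUMT read exclusion, inherited
    variants, VAF/depth cutoffs), six-class mutation spectra and
    frequencies, heteroplasmic-clone detection, a clonality-weighted
    Poisson expected-versus-observed clone-spectrum model, and the group
    comparison statistics used to report such studies (Welch's t-test,
    ANOVA with Tukey HSD, Dunnett contrasts, Fieller ratio confidence
    intervals, and frequency-versus-age regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    multcomp,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    VariantAnnotation,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
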