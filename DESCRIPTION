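Package: epirilqtl
Title: Epigenetic QTL Mapping and Trans-Acting Small-RNA Discovery in epiRIL Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps metabolite and expression variation in epigenetic recombinant
    inbred line (epiRIL) populations to differentially methylated regions used
    as genetic markers (QTL-epi), using Haley-Knott interval mapping with
    permutation-derived genome-wide LOD thresholds, multiple-QTL cofactor
    models with backward elimination, and 1.5-LOD support intervals. Scores
    probe-level methylation from unmethylated/methylated posterior
    probabilities, runs a staged cis-candidate funnel (interval membership,
    pathway filter, methylation-trait association, marker cosegregation,
    ranking), and nominates trans targets via maximal exact-match segments
    between QTL intervals and distal gene promoters, in-silico decomposition
    into 21-24 nt artificial small RNAs, ARGONAUTE-loading scoring, small-RNA
    library matching and transposable-element proximity. Ships a synthetic
    epiRIL data generator with known ground truth so every stage is testable
    by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
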