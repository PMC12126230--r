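Package: apascan
Title: Alternative Polyadenylation Detection from 3' UTR RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alternative polyadenylation (APA) from bulk RNA-seq
    coverage over annotated 3' UTRs. A de novo proximal polyadenylation site
    is located in each UTR by a two-segment least-squares regression fitted
    jointly across samples, yielding per-sample long- and short-isoform
    abundances and the Percentage of Distal poly(A) site Usage Index (PDUI).
    Differential APA between conditions is called from replicate-averaged
    PDUI differences with Welch or Fisher tests and Benjamini-Hochberg FDR
    control. APA gene sets can be intersected with RNA-binding-protein
    binding-site intervals (including a polyadenylation-site proximity rule)
    and tested for overlap against other gene lists with exact
    hypergeometric tests. A synthetic two-isoform coverage simulator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
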