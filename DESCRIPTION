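Package: nsafpipe
Title: Spectral-Count Proteomics with NSAF Quantification and
    Presence-Aware Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Label-free quantitative proteomics from protein-level
    spectral (PSM) counts: normalized spectral abundance factor (NSAF)
    quantification, replicate-presence filtering, a three-condition
    differential-expression rule that combines a t-test with
    presence/absence evidence and a signed fold-change threshold,
    principal-component analysis with loading-sum summaries, k-means
    clustering of proportion-normalized treatment profiles,
    hypergeometric GO-term enrichment with Benjamini-Hochberg FDR
    control, functional-bin categorization and Venn set comparisons.
    Includes a multinomial spectral-count simulator with
    abundance-dependent detection dropout, modelled on a four-treatment,
    three-replicate tomato pollen heat-stress and ethephon study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
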