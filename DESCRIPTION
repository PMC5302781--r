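Package: spongenet
Title: miRNA-Mediated ceRNA Network Inference and Isoform Titration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA, "miRNA sponge") interaction
    networks from paired expression profiles of mRNAs, long non-coding RNAs and
    miRNAs. Candidate sponge pairs are screened by Pearson correlation, the
    miRNA's mediating role is quantified by the sensitivity correlation (Pearson
    minus partial correlation conditioned on the miRNA), candidates are
    restricted by 6-mer seed-match sharing and hypergeometric enrichment of
    binding sites, and the surviving triplets are assembled into a multigraph of
    miRNA-labelled sponge interactions. A companion isoform-level toolkit
    implements paired t-test filtering, abundance shares, variation matrices,
    covariance PCA and isoform-to-miRNA abundance ratios for titration analysis.
    A synthetic-data generator with analytically known correlation structure
    provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
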