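Package: panpep
Title: Minimal Surrogate Peptide Panels Covering Bacterial Panallelomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a nonredundant protein database (panallelome) from
    directories of bacterial proteome FASTA amino-acid files, selects the
    allelic variants of a user-supplied reference protein, and computes a
    minimal list of tryptic peptide sequences that covers every retained
    variant, for use as surrogate peptides in targeted proteomics or as
    protein-detection motifs in genomic data. Includes per-genome quality
    screening, in-silico protease digestion with multi-copy peptide
    detection, exact incremental deduplication with full cluster-membership
    tracking, pairwise global and local protein alignment filters, greedy
    set-cover peptide selection, specificity validation with cleavage-context
    checks, and a deterministic synthetic proteome generator with planted
    ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
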