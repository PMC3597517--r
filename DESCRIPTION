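Package: junctionsig
Title: Breakpoint Junction Signatures of Non-Recurrent Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of breakpoint junctions of non-recurrent genomic
    deletions. Calls microhomology, inserted nucleotides and information
    scars at sequenced deletion junctions; scans 150-bp breakpoint regions
    for rearrangement-associated sequence motifs, non-B DNA-forming
    sequences (direct, inverted and mirror repeats, G-quadruplex candidates,
    Z-DNA-compatible alternating tracts) and repeat-element context; builds
    seeded random control populations of artificial breakpoint regions and
    tests enrichment with exact statistics; and classifies the candidate
    repair mechanism (NHEJ, MMEJ, NAHR, replicative template switching)
    from the junction signature. Ships a curated fixture of 24 fine-mapped
    FOXL2-locus microdeletions and a synthetic-data generator that plants
    junctions with known signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
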