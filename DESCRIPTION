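Package: dsbmapr
Title: Mapping AID-Dependent DNA Double-Strand Breaks from Strand-Oriented ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies off-target DNA double-strand breaks (DSBs) from
    Nbs1 ChIP-Seq tag libraries by control-referenced peak calling with
    tiered tag-count filters, classifies one-ended versus two-ended breaks
    by strand bias and read-orientation signatures, characterises break
    sites for WGCW-hotspot and CA (Z-DNA) tandem repeats with an
    indel-free repeat finder, and assesses interval co-occurrence with
    matched-random-interval permutation tests. Ships a fully seeded
    synthetic-data generator (genome with planted repeat arrays, break
    sites with the DSB read-orientation model, background sonication
    reads) and truth-based recovery scoring so the whole pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    IRanges,
    S4Vectors,
    Biostrings,
    generics,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
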