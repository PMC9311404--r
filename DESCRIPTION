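Package: sltscan
Title: Detection and Consequence Analysis of Spliced-Leader Trans-Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spliced-leader (SL) trans-splicing in transcriptomes:
    finds the conserved SL motif in assembled transcripts and in aligned
    reads, calls supported SL addition sites on coding sequences, screens
    gene models for 5'-misprediction with a sliding-window spanning-read
    test, identifies SL-truncated transcript variants and classifies their
    predicted protein consequences, surveys genome assemblies for SL RNA
    loci and mRNA-recycling candidates, and compares expression (TPM) of
    genes with and without SL addition sites. Includes a synthetic-data
    generator with a planted ground-truth manifest so the whole pipeline
    can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicAlignments,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
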