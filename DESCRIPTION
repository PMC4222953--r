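Package: altss
Title: Alternate 5'/3' Splice-Site Choice Analysis from Junction Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and characterization of alternate 5' and 3' splice-site
    (A5C/A3C) events from splice-junction read counts. Enumerates candidate
    events as junction pairs sharing one boundary, depletes cassette-exon
    look-alikes against an exon annotation, tests differential usage with
    percent-spliced-in (psi) differences and Fisher's exact test across
    knockdown contrasts, classifies the predicted mRNA consequence of each
    event (5'UTR/3'UTR change, ORF change, premature termination codon with or
    without predicted nonsense-mediated decay), and compares regulatory
    classes by polypyrimidine-tract motif density and donor splice-site
    strength asymmetry. A synthetic-data generator emits genome, annotation,
    junction counts and ground-truth labels so the whole pipeline can be
    validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
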