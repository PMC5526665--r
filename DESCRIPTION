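Package: hgtscan
Title: Detection of Horizontally Transferred Genomic Islands in Bacterial Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative horizontally transferred genomic regions among
    annotated bacterial genomes. All protein-coding sequences are compared
    across genomes with a seed-and-extend nucleotide local aligner (or with
    imported tabular hits from an external search tool), near-identical hits
    between distinct species are filtered against fragment-based average
    nucleotide identity (ANI) to remove vertically inherited similarity,
    surviving candidate genes are assembled into genomic islands by proximity,
    and islands sharing genes across genomes are clustered into groups.
    Includes functional-category tallies over the detected gene set, screening
    of marker islands against assembled metagenomes, and a seeded synthetic
    community generator with planted transfers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
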