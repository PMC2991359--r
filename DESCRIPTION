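Package: cladecompare
Title: Comparative Genomics of Small Bacterial Clades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale comparative analysis of a clade of
    annotated bacterial genomes: genome summary statistics, windowed G+C
    content and GC skew, codon usage and upstream regulator-motif scanning;
    protein best-hit filtering and reciprocal-best-hit orthology; pan-genome
    core/accessory partitioning and COG profiling; gene-order synteny block
    detection by dynamic programming; insertion-sequence census, cluster
    scanning and nested-insertion detection; circular-atlas track export and
    tabular reports. Includes a synthetic genome-clade generator with ground
    truth (ortholog families, planted inversions, IS expansions, GC-offset
    islands) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
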