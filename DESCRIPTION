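Package: splicetrace
Title: Gene-Structure Phylogenomics of the PRPS Enzyme Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the origins of paralogous gene families from
    exon-intron gene structure. Parses strand-aware gene models, validates
    splice junctions (canonical GT/AG, non-canonical GC/AG), computes intron
    positions with codon phase, and projects them onto protein multiple
    alignments to call splice junctions conserved across paralogs. Annotates
    candidate family members in assembled transcripts by six-frame ORF
    extraction and local alignment against a reference panel, detects long
    lineage-specific loop insertions (non-homologous regions), scores
    conservation of catalytic and interface residue sets, measures how amino
    acid differences concentrate in a sequence window, and finds upstream
    in-frame alternative translation start sites. Per-sequence features feed a
    rule-based homolog classifier, clade presence/absence profiles, and
    bootstrap support for duplication origins. A seeded gene-family simulator
    with a ground-truth event log makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
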