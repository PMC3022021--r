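Package: pangcn
Title: Bacterial Pan-Genome Analysis and Genome-Context-Network Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics toolkit for closely related bacterial
    strains: genome statistics (GC, GC3, coding fraction), detection of
    large duplicated chromosomal segments, reciprocal-best-hit orthology
    and paralog families, three-way pan-genome partition with per-ortholog
    variant classification, Nei-Gojobori (1986) dN/dS estimation with
    Jukes-Cantor correction, codon adaptation index, metabolic-pathway
    presence matrices, and genome-context-network (phylogenetic profile /
    gene neighbor / gene fusion) phylogenies with neighbor-joining trees
    and panel bootstrap. Includes a synthetic pan-genome simulator that
    evolves strain triplets from a common ancestor with known ground
    truth, so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
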