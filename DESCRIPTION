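Package: tefam
Title: Gene-Family Expansion Analysis with Transposable-Element
    Co-Localization and Motif Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing tandemly expanded gene families in draft
    genome assemblies. Discovers candidate family loci by exon-level
    Smith-Waterman homology scanning and classifies each locus as an intact
    gene or a pseudogene from frameshift, nonsense and exon-integrity rules;
    tests transposable-element (TE) co-localization around family loci with a
    random-window permutation null, builds strand-oriented binned meta-locus
    TE density profiles with satellite-peak detection, and compares TE-family
    composition between focal loci and the whole genome; classifies isoprenyl
    diphosphate synthase (IDS) proteins into canonical and divergent clades
    from aspartate-rich (DDxxD) and insect-GGPPS motifs. A synthetic-genome
    generator with planted paralog clusters, lesions and TE landscapes
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
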