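Package: cicerArrayQTL
Title: SNP Array Design, Genotype QC, Linkage Mapping and ICIM QTL Analysis for Chickpea-Style RIL Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for designing Axiom-style SNP genotyping
    arrays and analysing the genotypes they produce in biparental
    recombinant inbred line (RIL) populations. Implements candidate-SNP
    selection from a variant panel (flanking-SNP isolation, SSR, indel,
    biallelic, minor allele frequency, GC content, ambiguity and quality
    filters, deduplication and genomic-region/coding-effect annotation),
    Axiom best-practice sample and SNP quality control (call rate, FLD,
    HetSO, HomRO cluster metrics and category assignment), RIL genetic-map
    construction (1:1 segregation test, duplicate binning, recombination
    fraction and LOD estimation with selfed-RIL correction, single-linkage
    grouping, seriation with ripple, Kosambi distances) and additive
    inclusive composite interval mapping (stepwise cofactor selection,
    interval scanning, permutation LOD thresholds and
    robust/stable/consistent QTL categorisation). A synthetic-data module
    generates reference genomes, variant panels, RIL genotypes, phenotypes
    with planted QTLs and cluster-signal summaries with known ground truth
    so every stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
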