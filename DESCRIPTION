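Package: mutmapr
Title: Candidate Mutation Mapping from Comparative Whole-Genome Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate causative mutations in resequenced
    haploid mutant strains by comparative analysis across a cohort. Variants are
    classified against gene models (synonymous, nonsynonymous, nonsense,
    frameshift, splice site, UTR, intron, intergenic), compared across strains
    through a variant-occurrence matrix, restricted to genetically mapped marker
    intervals, and ranked by effect severity with cross-strain exclusion and
    knockout-phenotype corroboration. Also computes cohort polymorphism
    summaries: per-strain category tables, occurrence spectra, indel size
    spectra and their coding-sequence bias, sliding-window divergence profiles
    with haplotype-block segmentation, transition/transversion ratios, and
    spontaneous mutation-rate estimates. A synthetic-cohort generator emulates
    the polymorphism structure of a multi-strain fungal resequencing panel so
    every stage can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    Matrix,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
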