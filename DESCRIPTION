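Package: mendelsieve
Title: Family-Based Exome Variant Prioritization for Rare Retinal Disease
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease variants in multi-sample exome VCFs
    using nuclear-family pedigrees. Implements the classic rare-disease triage
    funnel: population allele-frequency filtering, transcript-isoform-aware
    consequence annotation, Mendelian segregation models (autosomal recessive
    homozygous, compound heterozygous with trans-phase inference from parental
    genotypes, and autosomal dominant with an incomplete-penetrance mode),
    gene-panel intersection and unconditional review of known disease genes.
    Also provides gene-drop pedigree simulation for benchmarking, a packaged
    four-family bestrophinopathy-style fixture with a two-isoform toy gene,
    and split-read counting of isoform-discriminating splice junctions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    vcfR,
    Biostrings,
    GenomicAlignments,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
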