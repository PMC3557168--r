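Package: rrlsnp
Title: SNP Discovery and Genotyping-by-Sequencing Validation for
    Reduced-Representation Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pileup-based discovery of single-nucleotide polymorphisms from
    reduced-representation sequencing libraries of multiple inbred genotypes,
    with a depth/consensus/context filter stack (minimum read depth,
    per-genotype maximum-depth cutoff at the mean plus two standard
    deviations, consensus base ratio, quality, homopolymer and adjacent-SNP
    removal), genome-binned coverage statistics (mapping coverage percentage
    and mapped read depth in fixed-width bins of the concatenated reference),
    SNP characterization (transition/transversion classes,
    genic/intergenic/CDS partition, cross-genotype sharing, discovery rates),
    and validation of candidate SNPs by segregation in a recombinant inbred
    line population genotyped by sequencing. A built-in simulator performs
    in-silico restriction digests with fragment size selection and emits
    reference genomes, pileups, gene models and RIL populations with exported
    truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
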