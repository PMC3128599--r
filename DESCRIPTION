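Package: autozyg
Title: Homozygosity Mapping of Autosomal-Recessive Trait Loci from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps autosomal-recessive Mendelian trait loci by consensus
    homozygosity (autozygosity) scanning of Illumina-style A/B SNP-array
    genotypes in a group of affected, related individuals, with a
    carrier-heterozygosity re-check. Includes per-SNP quality-control
    filtering (call rate, GenTrain score), extraction of maximal runs of
    consensus-homozygous loci, gene-content annotation of candidate regions
    from BED intervals, downstream mutation analyses (coding-sequence
    translation, nonsense-variant classification, in-silico PCR-RFLP digest
    band prediction, recessive-model genotype-phenotype concordance),
    two-locus haplotype-frequency estimation by EM with r-squared and D-prime,
    and a pedigree-based synthetic cohort generator that plants autozygous
    segments around a causal allele for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
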