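Package: madcpop
Title: Microhaplotype Read-Count (MADC) Processing and Population Genetics for Targeted Amplicon Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes missing allele discovery count (MADC) reports from
    targeted amplicon genotyping panels (DArTag-style microhaplotype read
    counts) into SNP genotypes and downstream population-genetic summaries.
    Includes microhaplotype-level quality control (singleton zeroing,
    single-plant versus bulked-sample diversity accounting), alignment-based
    target and off-target SNP extraction with VCF export, presence and
    Hind/He genotype filtering, allele-dosage calling, PCA, Weir-Cockerham
    FST, Welch ANOVA with Games-Howell post hoc tests, Tamura-Nei
    neighbor-joining phylogeny with bootstrap support, and nearest-neighbour
    taxonomic mislabel flagging. A synthetic-data generator emulates
    cross-species marker transferability (divergence-dependent locus
    dropout, Balding-Nichols differentiation, selfing, replicate and bulked
    sampling, sequencing error) so the whole pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
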