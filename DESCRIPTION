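Package: haplodose
Title: Haplotype-Dosage Non-Invasive Prenatal Diagnosis from Maternal
    Plasma Cell-Free DNA
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers which parental haplotypes (pathogenic versus wild-type)
    a fetus inherited at an autosomal-recessive locus, from targeted
    sequencing of a family trio (father, mother, affected proband) and of
    maternal plasma cell-free DNA. Informative SNPs in the target region
    are anchored to parental haplotypes through the affected proband and
    divided into eight genotype groups; the fetal fraction of cell-free
    DNA is estimated from paternal-specific alleles; and a per-parent
    weighting product over group-level allele-ratio deviations (the
    S-value) calls each inherited haplotype as pathogenic, wild-type or
    inconclusive. Includes a synthetic-family simulator producing phased
    haplotypes, trio genotypes and plasma read counts under a binomial
    mixture model, so the whole pipeline can be exercised and benchmarked
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml
biocViews: Genetics, SNP, VariantDetection, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
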