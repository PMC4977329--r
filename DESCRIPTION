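Package: pedblock
Title: Consistent Phased Haploblock Genotypes in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives consistent, phased, multi-allelic haploblock genotypes
    for all individuals in a multi-generation pedigree from phased bi- or
    multi-allelic marker data. Closely linked, map-contiguous markers are
    treated as a single multi-allelic locus (a haploblock); each distinct
    marker-haplotype observed in the pedigree becomes a numbered haploblock
    allele. An iterative half-sib-family resolution algorithm imputes missing
    marker data, detects and rejects conflicting data, and converges on a
    configuration in which every transmitted allele is consistent between
    parent and offspring. Includes a gene-drop simulator with a hidden truth
    set and evaluation metrics (imputation accuracy, Mendelian consistency
    audit, informative-meiosis fractions), plus readers and writers for
    tab-delimited linkage map, haploblock, pedigree and phased genotype
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
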