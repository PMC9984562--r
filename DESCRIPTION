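Package: amitools
Title: Detection of Admixture-Source-Derived Variants with the Ancestry-Marker Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects variants inherited from a diverged admixture source in an
    admixed population using the ancestry-marker index (AMI), a linkage-
    disequilibrium summary computed over population-specific variants. Includes
    a coalescent validation simulator with per-haplotype ancestry truth
    (driving msprime), ROC/Youden threshold selection, a per-individual
    marker-allele ancestry score (JAS), haplotype-based ancestral allele-
    frequency estimation, polygenic mean-2-beta-f trait divergence statistics
    with a permutation null, outgroup f3 statistics, and an S* comparator for
    archaic-scale versus recent divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
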