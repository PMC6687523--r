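Package: transxcan
Title: Mapping Trans-Acting Regulator Genes from Predicted Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps trans-acting regulator/target gene pairs by correlating the
    cis-genetic component of gene expression (GReX), predicted from genotype
    dosages with elastic-net weight tables, against observed expression of
    genes on other chromosomes. Implements a single-tissue standardized
    correlation scan with per-tissue Benjamini-Hochberg FDR, a multi-tissue
    principal-component regression scan with an F-test of the joint fit,
    Storey-style pi1 replication statistics, k-mer gene mappability and
    cross-mappability quality control, hypergeometric gene-set enrichment,
    and a chromosome-matched permutation null for overlap with an external
    trans-eQTL reference. A synthetic multi-tissue genotype-transcriptome
    cohort simulator with known cis and trans architecture makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    RSQLite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
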