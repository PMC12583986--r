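Package: hopanotype
Title: Genotype to Chemotype Inference for Hopanoid Production in Alphaproteobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hopanoid (hpn) biosynthesis genes in annotated bacterial
    genomes by local protein alignment with percent-similarity thresholds,
    groups accepted hits into candidate biosynthetic gene clusters, and applies
    biosynthesis logic to predict the classes of bacteriohopanepolyol
    derivatives (BHPDs) a strain can produce. Implements the measurement-side
    arithmetic of hopanoid lipidomics (internal-standard quantification of
    periodate/borohydride degradation products, MRM-based degree of ring-A
    methylation, C-22 epimer fractions, inventory summaries), an in-silico
    Rohmer degradation that maps intact BHPD structures to GC-amenable
    hopanols, genotype-versus-phenotype concordance statistics, and a
    synthetic genome/lipidome generator with known ground truth for end-to-end
    validation. Ships a curated gene-family catalog and transcribed reference
    tables for a 54-species Alphaproteobacteria culture panel.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
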