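Package: sporesigma
Title: Classification and Phenotypic Analysis of Phage-Encoded Sporulation-Like Sigma Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for studying sporulation-like sigma factors carried by
    bacteriophages of endospore-forming hosts. Classifies sigma-factor proteins
    from homology-search hit tables with a best-hit rule and general-family
    fallback, calls sporulation-clade membership on annotated phylogenies while
    excluding the sigB subclade, computes a phage virulence index from
    plate-reader growth curves over an MOI dilution series, gates flow-cytometry
    events into spores and vegetative cells with an asinh/singlet/noise/
    Gaussian-mixture chain and derives spore yields, and post-processes
    differential-expression tables with hypergeometric sporulation-gene
    enrichment. Seeded synthetic-data generators emulate every input so each
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    phangorn,
    pracma,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
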