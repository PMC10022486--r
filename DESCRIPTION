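Package: evomics
Title: Desk-Scale Genome Evolution and Expression-Metabolome Integration Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of a chromosome-level plant
    genome study: Nei-Gojobori (NG86) estimation of synonymous (Ks) and
    nonsynonymous (Ka) substitution rates with Jukes-Cantor correction,
    kernel-density modelling of Ks distributions and rate-calibrated dating
    of whole-genome duplication (WGD) events, detection of telomeric
    heptamer arrays (CCCTAAA/TTTAGGG) and centromeric tandem-repeat
    satellites on assembled chromosomes, WGCNA-style co-expression module
    detection with module-trait correlation, and metabolite abundance
    clustering with accumulation-rate statistics and module-metabolite
    integration. Seeded simulators generate codon pairs, chromosomes with
    planted repeats, expression matrices with planted modules, and
    metabolite time courses, so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
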