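Package: biallelic
Title: Detection and Simulation of Biallelic Somatic Mutations in Tumour Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling violations of the infinite sites assumption
    in bulk tumour sequencing data. Implements two simulators of biallelic
    parallel and divergent somatic mutations (uniform permutation over
    callable trinucleotide contexts and neighbour resampling from matched
    tumour cohorts), a variant-allele-frequency caller based on a
    purity- and copy-number-corrected beta-binomial model with its full
    quality-filter cascade, a read-backed phasing caller with precision and
    recall evaluation and burden extrapolation, closed-form birthday-problem
    collision estimators, and a synthetic tumour cohort generator with truth
    manifests for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    vcfR,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
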