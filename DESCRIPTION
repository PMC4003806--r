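Package: bsaHMM
Title: QTL Mapping from Bulk-Segregant Pooled Sequencing with a Hidden
    Markov Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTL) from bulk-segregant
    analysis (BSA) pooled-sequencing allele counts. A two-state hidden
    Markov model with beta-binomial emissions captures overdispersed
    pooled allele counts, while distance-dependent transition
    probabilities exploit linkage disequilibrium between neighboring
    marker sites to separate phenotype-linked regions from spurious
    allele-frequency deviations. Includes marker-table input/output and
    filtering, forward-backward posterior decoding with region calling, a
    meiotic-recombination pool-sequencing simulator, replicate benchmark
    metrics (recovery rate, linked-region size, false-positive regions),
    and individual-segregant validation statistics based on exact
    binomial tests with Benjamini-Yekutieli FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
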