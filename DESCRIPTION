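Package: plastfirst
Title: Gene Expression Plasticity and Genetic Divergence Across
    High-Elevation Colonization Stages
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies gene expression plasticity across three stages of
    high-elevation colonization (ancestral, plastic, colonized) into
    reinforcement and reversion responses, with magnitude categories,
    parametric-bootstrap support and exact binomial excess tests.
    Phenotype-correlated genes are called as positive or negative
    regulators and their plastic changes as adaptive or maladaptive.
    Genetic divergence around candidate genes is quantified with the
    Weir-Cockerham FST estimator and a background-resampling permutation
    test over genic and 2 kb flanking regions. A synthetic-data generator
    with known ground truth (log-normal expression noise, linearly
    coupled phenotypes, Balding-Nichols genotypes) makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
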