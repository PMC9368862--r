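Package: edmap
Title: Euclidean-Distance Bulked-Segregant Mapping of EMS-Induced Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Isolates EMS-induced causal mutations from pooled whole-genome
    sequencing of phenotype-selected bulks (MutMap+-style designs in selfed
    progeny of heterozygous plants). Implements a per-SNP Euclidean-distance
    allele-frequency statistic with read-support QC, local tricube smoothing,
    threshold computation and candidate-interval calling; codon-level variant
    effect annotation against gene models with nonsynonymous candidate
    filtering and protein-motif (degron) checks; Mendelian segregation-ratio
    chi-square tests; recombinant-breakpoint fine mapping from ordered marker
    genotypes; and a fully seeded synthetic-data generator (EMS mutation
    spectra, F2 cohorts under the Haldane map function, phenotype-selected
    pools and pooled read counts) used to validate the whole pipeline
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
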