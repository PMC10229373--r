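Package: organellr
Title: Classification of Organellar DNA in Eukaryotic Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies each sequence (contig or scaffold) of a eukaryotic
    genome assembly as nuclear, mitochondrial, or plastid DNA. Intrinsic
    sequence features (GC content, assembly-relative GC deviation, sequence
    length, CpG islands detected by a sliding-window scan) are combined with
    per-megabase densities of annotation evidence ingested from standard
    files (repeat and rRNA intervals in GFF3, tRNA scanner tabular output,
    blast-style protein homology hits against mitochondrial and plastid gene
    sets). A stratified cross-validation protocol selects among linear,
    random-forest, k-nearest-neighbour, and AdaBoost classifiers; evaluation
    reports one-vs-rest confusion counts with Matthews correlation
    coefficient, F1, precision, sensitivity, and specificity. A seeded
    synthetic-assembly generator produces complete fixture bundles so the
    whole pipeline is testable without external annotators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    nnet,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
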