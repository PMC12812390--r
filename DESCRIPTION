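Package: nanoepisign
Title: DNA Methylation Episignature Detection from Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts long-read 5mC methylation calls (bedMethyl, modkit
    dialect) into array-compatible probe-level beta values, harmonizes probe
    identifiers across Illumina MethylationEPIC manifest versions, and detects
    disorder-specific DNA methylation episignatures. Analytics cover
    cross-platform Pearson concordance, hierarchical clustering (Euclidean,
    complete linkage), classical multidimensional scaling, a seeded UMAP
    embedding, and reference-based classification via a nearest-centroid score
    and a linear support-vector machine with leave-one-out validation. A
    binomial read-count simulator generates manifests, reference beta matrices
    and per-sample bedMethyl files with the statistical structure the analysis
    assumes, so the full pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    cluster,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
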