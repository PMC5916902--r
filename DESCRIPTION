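Package: rbptools
Type: Package
Title: Harmonizing RNA-Binding Protein Interactomes and Quantifying
    Post-Transcriptional Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how an RNA-binding protein shapes the fate of
    its target mRNAs. Harmonizes heterogeneous protein-RNA association
    datasets (CRAC crosslink counts, RIP microarray scores, CLIP binary
    calls) into a common 0-1 binding matrix with quartile binding
    categories; tests gene sets for enrichment among an RBP's preferred
    targets with a running-sum statistic and a permutation null; quantifies
    RNA immunoprecipitation by qPCR relative quantification (percent of
    input, fold over a no-tag control); turns sucrose-gradient fraction
    quantities into spike-corrected distributions and translated
    proportions; fits exponential decay to cycloheximide-chase series to
    estimate protein half-lives; and averages dye-swap microarray
    replicates with a replicate-consistency filter and binding-category
    stratification. A seeded synthetic-data generator with full ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
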