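Package: pseudoscan
Title: Homology-Based Functionality Classification of Multi-Exon Gene
    Copies in Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates copies of multi-exon genes (developed for the Tas1r
    umami/sweet taste-receptor family) in genome assemblies by translated
    homology search, reconstructs their exon structure, diagnoses
    open-reading-frame disruptions (frameshift indels and premature stop
    codons), counts predicted transmembrane helices, and classifies each
    gene copy as intact, partial, defective (pseudogene), or absent, with
    synteny-based verification of absence through the gene's two flanking
    genes.  Includes a synthetic-genome simulator that plants gene copies
    in every functionality state with full ground truth, so the whole
    pipeline can be exercised and validated without downloading any
    assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    withr
Config/testthat/edition: 3
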