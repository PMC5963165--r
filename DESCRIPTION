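Package: metatx
Title: Metatranscriptome Functional Annotation, Aggregation and Differential Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale metatranscriptome analysis toolkit: parses protein
    reference databases with organism-in-brackets FASTA headers and a
    four-level functional hierarchy table, selects best hits from BLAST
    tabular (outfmt 6) aligner output, joins hits to per-read organism and
    function annotations, condenses annotations into sorted abundance counts
    with hierarchy rollups and organism/function data slicing, and computes
    cross-sample statistics (median-of-ratios normalization, diversity
    indices, PCA coordinates, two-group differential activity with
    Benjamini-Hochberg FDR control). Includes a small translated-search
    aligner over a peptide k-mer index, simplified paired-read merging,
    quality trimming and rRNA filtering, and a seed-deterministic simulator
    that generates mock reference databases and provenance-tracked reads so
    annotation accuracy can be evaluated end to end without external tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
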