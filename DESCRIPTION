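Package: genotab
Title: Merge, Filter, Reduce and Convert Character-Delimited Genomic Data Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable engine for processing character-delimited genomic
    data files of any dialect. Reads arbitrary delimited text, VCF (with
    flattening of canonical and non-canonical INFO keys), BED, GFF/GTF, PSL
    and WIG into one universal table model; merges tables horizontally by
    genomic location (overlap or exact-interval joins) or by up to four key
    columns, and vertically by column-name union; filters rows by column
    predicates, by external value lists, by external genomic criteria tracks,
    and by presence across samples; reduces tables by column selection and
    deduplication; and exports to tab-delimited text and the UCSC/ENCODE
    custom-track formats (BED, BED detail, GFF, PSL, pgSnp, BED6+3,
    narrowPeak, broadPeak, gappedPeak, peptideMapping). Pipelines of these
    steps can be described in YAML configuration files and run from a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
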