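Package: refassets
Title: Reference Genome Asset Management, Archiving and Retrieval
Version: 0.1.0
Authors@R:
    person("refassets", "developers", email = "refassets@example.org",
           role = c("aut", "cre"))
Description: Manager for reference-genome-associated resources ("assets"):
    sequences, aligner indexes and annotation bundles are organized under a
    standard on-disk layout, identified by human-readable registry paths
    (genome/asset:tag), and tracked in a YAML genome configuration file.
    Assets are built from recipes (including FASTA indexing into FAI and
    chromosome sizes), fingerprinted with order- and location-independent
    content digests, archived into per-asset tarballs served over a
    REST-style HTTP API, and pulled from such servers with digest-verified
    integrity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    callr,
    curl,
    digest,
    filelock,
    httpuv,
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
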