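Package: enfragility
Title: Enhancer Fragility from Predicted Deactivating Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies enhancers into fragile, regular and stable classes by
    their density of predicted deactivating mutations (deMs). A linear
    classifier scores every candidate substitution that flips an enriched
    ("top") k-mer to an unenriched ("background") one, decomposes the score
    into a motif-disruption term WS(Delta) and a neighborhood-context term
    WS(S), and calls deM positions at a false-positive-rate calibrated
    threshold. The package ships a fully specified synthetic-world generator
    (genomes with planted homotypic and heterotypic binding-site
    architectures, chromatin signal tracks, labeled training variants, an LD
    panel and evolutionary masks), GC/repeat/length-matched control sampling,
    Fisher-enrichment k-mer vocabularies, PSSM scanning with
    false-positive-density calibration, homotypic/heterotypic cluster typing,
    and evolutionary-constraint and GWAS disease-type enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    stringi,
    e1071,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
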