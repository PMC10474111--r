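Package: iibprofiler
Title: Metagenomic Profiling from Type IIB Restriction Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species identification and taxonomic-abundance estimation from
    whole-metagenome shotgun reads using in-silico extracted Type IIB
    restriction fragments ("2b tags"). Builds species-specific tag databases
    from genome collections, profiles samples in two rounds of exact tag
    matching with a machine-learning false-positive filter between rounds,
    and ships a ground-truth shotgun-read simulator plus identification and
    abundance-similarity metrics so the whole method can be benchmarked
    end to end on synthetic communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
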