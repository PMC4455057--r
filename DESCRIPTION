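Package: hgtcensus
Title: Census of Horizontal Gene Transfer into Archaeal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and summarises horizontal gene transfer (HGT) from
    bacteria into a focal archaeal genus and family. Builds groups of
    orthologous proteins (GOPs) from bidirectional-best-hit similarity
    searches with a paralog rule, screens them for bacterial-type
    similarity profiles, constructs bootstrapped neighbor-joining trees of
    homolog sets, roots them by taxonomy-aware rules and calls transfer
    events with timing (family ancestor, genus ancestor, species specific)
    and a donor taxon. Includes census statistics (year-stamped database
    trajectory, donor overrepresentation, COG-category enrichment, 2x2
    chi-square comparisons, expression tallies), operon prediction from
    intergenic distances with transferred-fragment lengths, and a
    truth-labelled synthetic-universe generator (taxonomy, species tree,
    gene families with planted transfers, genome layouts) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
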