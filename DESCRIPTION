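Package: foldcons
Title: Consensus Fold Assignment for Uncharacterized Protein Domain Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for large-scale remote-similarity surveys
    of protein domain families with unknown structure and function. Reads hit
    tables produced by five complementary search strategies (profile HMM
    searches against linker-enriched and natural SCOP sequence databases,
    profile-profile alignment, HMM-library scans, threading), applies each
    method's significance and coverage filters, collapses hits to a single
    SCOP superfamily per query region with per-method decision trees, merges
    methods by domain-region overlap into confidence-tiered consensus
    assignments, annotates assignments with Gene Ontology terms, candidate EC
    numbers and taxonomic kingdom distributions, and scores predictions
    against families of known structure. A deterministic synthetic-fixture
    generator emits complete input bundles in every supported file dialect so
    the whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
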