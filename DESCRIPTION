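Package: bioweave
Title: Desk-Scale Warehouse for Cross-Referenced Biological Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a local, embedded relational warehouse that integrates
    entities from the major public biological databases (NCBI Taxonomy and
    Gene, genome PTT coordinate tables, UniProt and UniRef, PSI-MI 2.5
    molecular-interaction sets, DrugBank, KEGG pathways and enzymes, and
    OBO-XML ontologies) under a single surrogate-key scheme with resolved
    cross-references. Provides strict transactional loaders that leave the
    store untouched on malformed input, a constraint-based text-search layer,
    graph builders for taxonomy trees, evidence-weighted protein-protein
    interaction networks and drug-pathway bipartite graphs, and worked
    multi-database queries such as chromosomal-neighborhood and ortholog
    drug-target scans. A declarative fixture generator serializes synthetic
    worlds into valid files of every supported source dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
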