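# bioweave

A desk-scale warehouse for cross-referenced biological databases, in R.

Questions that span several public data sources — *which antibiotics target
proteins encoded near this gene? do the orthologs of this gene across a
genus sit next to drug-target genes? which drugs act on the same metabolic
pathway, and in which organisms?* — need taxonomy, gene coordinates,
proteins, interactions, drugs and pathways joined in one place, plus graph
operations (subtree expansion, neighbor classification, shortest paths)
that are awkward in plain SQL. bioweave builds that place locally: a single
embedded relational store (SQLite via DBI) holding entities from the major
public source formats under one surrogate-key scheme, with resolved
cross-reference link tables, strict transactional loaders, a text-search
layer with composable constraints, and igraph-backed entity graphs.

It is aimed at bioinformaticians who want intensive, scriptable querying of
integrated data on a workstation — no server, no network.

## What it implements

* **Relational core.** Every entity row gets a warehouse-wide surrogate id
  (WID) from one strictly increasing counter. `schema_ddl()` emits plain
  standard-SQL DDL; classic warehouse SQL such as

  ```sql
  select p.seq from Protein p
    inner join ProteinAccessionNumber a on a.Protein_WID = p.WID
    where a.AccessionNumber = 'Q8DR59';
  ```

  runs verbatim against the emitted schema, and the test suite checks that
  SQL-level and API-level queries return identical rows.
* **Strict loaders** for NCBI taxdump, gene_info, PTT coordinate tables,
  UniProt / UniRef XML, PSI-MI 2.5 interaction XML, DrugBank XML, KEGG
  pathway/enzyme flat files and OBO-XML (documented subsets of each
  format). A load is all-or-nothing: any malformed consumed field aborts
  before the store is touched.
* **Search and links.** Case-insensitive substring search per entity kind,
  `IN`-constraints ("all proteins under this taxon"), and `linked()`
  traversal of resolved cross-references.
* **Graphs.** Taxonomy trees (directed, `|E| = |V| − 1`); PPI networks
  weighted by the number of distinct datasets reporting each interaction;
  drug–pathway bipartite graphs weighted by the size of the target∩member
  protein set; metrics, deterministic shortest paths, and a drug-neighbor
  classification into target / pathway (KEGG map-level) / distant /
  unreachable neighbors.
* **Case queries.** Chromosomal ±k-gene neighborhood drug-target scans,
  UniRef-cluster ortholog expansion of those scans over a taxonomic
  subtree, and sliding-window scans for regions dense in drug-target genes.
* **Fixture worlds.** A declarative generator serializes synthetic worlds
  into valid files of every supported dialect — including `paper_facts()`,
  a built-in world encoding printed public-record relations, and seeded
  `random_world()`s that the test suite checks against brute-force oracles.

## Worked example

```r
library(bioweave)

store <- wh_connect(":memory:")          # or a file path for persistence
load_world(store, paper_facts())         # write sources, parse, load, resolve

# Antibiotics targeting the ±10-gene neighborhood of gene spr0328
hits <- neighborhood_drug_targets(store, "spr0328", k = 10)
hits$drugs <- vapply(hits$drugs, paste, "", collapse = ",")
hits
#>   gene_id locus_tag protein_accession
#> 1  934791   spr0329            Q8DR59
#>                                                                     drugs
#> 1 DB00415,DB00456,DB00493,DB00567,DB00607,DB00713,DB00739,DB01061,DB01331
#>   offset
#> 1      1
```

One gene in the window encodes a drug target: spr0329 (GeneID 934791),
whose penicillin-binding protein Q8DR59 is hit by nine beta-lactams; it
sits one gene rank downstream of the query (`offset 1`).

```r
# Classify every other target-bearing drug relative to Hetacillin
nb <- drug_neighbors(store, "DB00739")
lengths(nb[c("target_neighbors", "pathway_neighbors", "unreachable")])
#>  target_neighbors pathway_neighbors       unreachable
#>                 8                 3                 1

# Organisms carrying Hetacillin's pathway at KEGG map level
drug_pathway_organisms(store, "DB00739")
#>    kegg_id map_number organism_tax_id
#> 1 cpe00550      00550          195102
#> 2 eco00550      00550          511145
#> 3 spr00550      00550          171101
```

Eight drugs share a target protein with Hetacillin; three more act on
peptidoglycan biosynthesis (map 00550) in other organisms — *S. pneumoniae*
R6 (171101), *E. coli* MG1655 (511145) and *C. perfringens* 13 (195102).

A command-line front end covers the same ground
(`exec/bioweave schema|fixtures|load|resolve|search|graph|drug-neighbors|example`),
writing TSV to stdout and logs to stderr; see `vignettes/bioweave-methods.Rmd`
for the model, dialect and design details.

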