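---
title: "bioweave: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bioweave: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Answering questions that span several public biological databases — "which
antibiotics act on proteins encoded near this gene?", "do the orthologs of
this gene in a whole genus sit next to drug-target genes?", "which drugs
act on the same metabolic pathway, in which organisms?" — requires joining
taxonomy, gene coordinates, protein records, interaction sets, drug-target
annotations and pathway membership. Doing that over web resources means
thousands of requests; doing it in a plain relational database makes the
recursive, graph-shaped parts of the question (subtree expansion, neighbor
classification, shortest paths) painful to express in SQL.

bioweave builds a *local* warehouse: strict parsers load files in the
public sources' formats into one embedded relational store, cross-references
between entities are resolved into link tables, and a query layer exposes
text search, link traversal, and graph constructions over the stored
entities. It is a desk-scale tool: the store is an embedded SQLite file
driven through DBI, and the emitted DDL is deliberately plain standard SQL
so the same schema loads into a server DBMS unchanged.

## The data model

Every entity row — taxonomy node, gene, PTT coordinate entry, protein,
interaction, UniRef cluster, drug, pathway, enzyme, ontology term — receives
a **WID**, a warehouse-wide surrogate integer drawn from a single strictly
increasing counter, so a WID is unique across all tables of a store and is
never reused. Natural keys (tax id, GeneID, primary accession, DrugBank id,
KEGG id, EC number, term id) are enforced unique per store; WIDs are
surrogates only.

Multi-valued fields (synonyms, accession lists, cluster members, drug
targets, pathway members) live in side tables carrying a `Position` column
so record order survives a round trip. Cross-references are materialized by
`resolve_crossrefs()` into `Entity_has_Other` link tables by joining natural
identifiers case-insensitively (`UPPER()` joins — standard SQL rather than a
collation clause, keeping the DDL portable). References that do not resolve
are counted and reported, never fabricated: source files legitimately
mention entities from modules that were not loaded, because modules can be
loaded independently.

Core table and column names (`Protein`, `ProteinAccessionNumber`,
`Protein_has_Taxonomy`, `TaxonomySynonym`, `WID`, `Seq`,
`AccessionNumber`, `Synonym`) are fixed so that SQL written against this
family of warehouse schemas — including the two published example
statements the test suite runs verbatim — executes unmodified.

## Strict, transactional loading

Public dumps are large and their syntax is loosely specified; a loader that
soldiers on past a malformed record can silently corrupt the warehouse. The
loaders here do the opposite: each parser consumes a *documented subset* of
its real format (the consumed elements are listed in the function
documentation), ignores unknown elements, and treats any malformed consumed
element as fatal. `wh_load()` parses and validates the entire file before
opening a write transaction, so a failed load leaves the store file
byte-identical; an insert-stage failure (e.g. a duplicate natural key when
a file is loaded twice) rolls back. The returned `parse_report` carries a
line/element locator for the failure.

Dialect decisions worth knowing:

* **Taxdump**: `"\t|\t"`-delimited nodes/names pair; a names row for an
  unknown tax id is fatal. Every loaded taxonomy batch must keep the store
  a single rooted tree (the root is its own parent).
* **PTT**: coordinates are 1-based inclusive (`start..end`); the strand is
  stored but deliberately unused by neighborhood logic. In this dialect the
  PID column carries the protein accession linking the entry to a protein
  record (real NCBI PTT files carry GI numbers there; how those map to
  protein records is source-release-specific, so the fixture dialect makes
  the link explicit). A PID of `-` means "no protein".
* **PSI-MI 2.5**: an n-ary interaction is expanded bait-versus-prey when a
  participant carries a `bait` experimental role, otherwise all-versus-all;
  this matches common practice. Self-interactions are retained as data but
  never become graph edges.
* **KEGG flat files**: the keyword field is fixed at 12 columns; `///` is
  optional before EOF (tolerant for hand-made files, strict where ambiguity
  would corrupt data). Pathway member proteins are listed as accessions
  directly (`MEMBER` lines); mapping KEGG gene identifiers to UniProt
  accessions is a documented extension point, not silently guessed.
* **UniProt/UniRef/DrugBank/OBO-XML**: namespaces are stripped before
  matching, so both real namespaced dumps and plain fixture files parse.
  The first accession of an entry is primary; a UniRef representative is
  guaranteed to appear among its cluster members; an accession may belong
  to at most one cluster.

## Search semantics

Matching is case-insensitive substring everywhere (`like '%term%'`), with
`exact = TRUE` for whole-identifier equality; an empty term matches every
record, which makes "all proteins under taxon X" expressible as an empty
search under a constraint. This is a deliberate unification: published
examples mix exact-looking SQL (`like 'human'`) with API synonym lookups,
and one coherent semantic plus an exact-match flag covers both. Only the
`IN` constraint operator exists (restricting a protein search to proteins
linked into a prior taxonomy result set); the operator list is extensible.
Results are ordered by ascending WID for reproducibility.

## Graphs

Graphs are igraph objects whose vertex names are `kind:natural-key`.
Distances are always hop counts — edge weights are evidence counts, not
lengths.

* **Taxonomy graph**: directed parent-to-child tree built by recursive
  descent from a root; for a loaded taxonomy it satisfies
  `|E| = |V| - 1`, acyclicity and full reachability from the root.
  Taxonomy edges are unweighted (no meaningful evidence count exists for a
  parent link).
* **PPI graph**: undirected; one edge per unordered protein pair, weighted
  by the number of *distinct* source datasets reporting the pair, so a
  pair reported by two datasets weighs 2 while a pair reported twice within
  one dataset weighs 1. Weights are therefore bounded by the number of
  loaded interaction datasets.
* **Drug-pathway graph**: undirected bipartite; an edge joins drug *d* and
  pathway *p* exactly when some protein is both a target of *d* and a
  member of *p*, weighted by the count of such proteins.

`drug_neighbors()` partitions every other drug holding at least one
resolved target into: **target neighbors** (share a target protein),
**pathway neighbors** (no shared target, but pathways containing targets of
both drugs share the organism-independent 5-digit KEGG map number), and
**distant neighbors** (reachable in the bipartite graph, annotated with hop
distance; the "nearest" distant neighbors are those at the minimum
distance), with the rest **unreachable**. Two design points deserve
emphasis. First, pathway identity is taken at *map level*: the
organism-prefixed pathways `spr00550` and `eco00550` count as the same
pathway, because cross-organism questions ("drugs acting on this pathway in
other organisms") are only meaningful there. Second, "nearest" is defined
as minimal bipartite hop distance among the drugs that are neither target
nor pathway neighbors; hop distance is the only distance the data
supports — metabolic-reaction adjacency is out of scope.

Shortest paths break ties lexicographically by vertex name (a two-sided BFS
keeps only vertices on some minimum-hop path and greedily picks the
smallest name at each step), so every path the package reports is
deterministic.

## The worked case queries

* `neighborhood_drug_targets(store, gene, k)`: the replicon's PTT entries
  are ordered by start coordinate and the window is ±`k` *gene ranks*
  (truncated at replicon ends), not base pairs — "±10 genes" is a rank
  statement. Each entry's PID maps to a protein and its drugs; entries with
  at least one drug are hits, the query gene included if it qualifies.
* `ortholog_neighborhood_scan()`: orthology is approximated by shared
  UniRef cluster membership — no sequence comparison is performed. The
  cluster members whose tax id falls in the taxonomy subtree are scanned
  and hits unioned, deduplicated by GeneID.
* `region_scan(store, root, max_len_bp, min_targets)`: per replicon, the
  drug-target genes are sorted by start and every maximal run of at least
  `min_targets` targets spanning at most `max_len_bp`
  (`max(end) − min(start) + 1`, 1-based inclusive) is reported; windows
  contained in a larger reported window are dropped, while overlapping
  non-nested windows remain separate hits (merging them could exceed the
  span bound). Replicons are treated as linear; circular chromosomes are a
  documented limitation. Enlarging `k`, the span, or the subtree never
  loses hits — only extends them — and hits are invariant under shuffling
  the input PTT row order, since sorting is internal.

## The fixture worlds

The package generates its own inputs. A fixture spec is a referentially
consistent set of record frames that `write_sources()` serializes into
valid files of *every* supported dialect, and the generate → write → parse
→ load → export loop is lossless (an acceptance-suite invariant).

`paper_facts()` encodes a small bacterial world around printed public-record
relations: gene spr0328 of *S. pneumoniae* R6 and its neighbor spr0329
(GeneID 934791) encoding the penicillin-binding protein Q8DR59 targeted by
nine beta-lactams; Hetacillin (DB00739) acting on PBPA_STRR6/PBP2_STRR6 in
the peptidoglycan-biosynthesis pathway spr00550; a TIGR4 ortholog
neighborhood whose gene 930269 encodes a drug target; TIGR4 target genes
930802/930805 within 5000 bp; and Ceftazidime/Cyclacillin acting on
map-00550 pathways of *E. coli* MG1655 and *C. perfringens* 13. Invented
details — all coordinates, sequences, filler entities, the synthetic TIGR4
strain taxid 1313901, and the DrugBank ids of the eight non-Hetacillin
antibiotics — are arbitrary and only preserve the printed order and
distance constraints (spr0329 adjacent to spr0328; the 930802/930805 pair
within 5000 bp; the distant block more than 10 gene ranks from the ortholog
window). Protein sequences are random 30-residue strings except where a
test pins a value.

`random_world(seed, sizes)` draws a referentially consistent world of
requested sizes through a single seeded RNG (identical seed, identical
world; the caller's RNG state is restored). Default sizes — 8 taxa, 2
replicons, 30 genes, 24 proteins, 4 clusters, 20 interactions over 2
datasets, 8 drugs, 6 pathways, 3 enzymes, 6 terms — keep a world at roughly
130 entities, small enough that the test suite can compare 50 seeded worlds
against brute-force oracles (quadratic region enumeration, all-pairs BFS,
set-algebra neighbor partitions recomputed directly from the spec's
relation tables) in well under a minute.

What the synthetic worlds do *not* emulate: real dump scale (hundreds of
gigabytes), the messiness of real annotation (obsolete accessions, secondary
accession reuse, inconsistent locus-tag casing beyond simple case folding),
KEGG gene-to-UniProt mapping, and circular replicons. Passing tests
demonstrate the correctness of the joins, weights and scans under the
documented dialects — not robustness to every artifact of real dumps.

## Numerical and degenerate-input choices

* Coordinates and spans are integer, 1-based inclusive throughout.
* PTT replicon ordering ties are broken by (start, end, locus tag).
* Empty graphs report all-zero metrics; the diameter is measured on the
  largest connected component, ignoring direction and weights.
* An empty world serializes to valid headers-only files and loads to an
  empty store; an empty record batch inserts zero rows.
* Batch validation happens against the combined (stored + batch) state, so
  a taxonomy batch may only be inserted if the union remains a single
  rooted tree.

## Known limitations

GenBank/RefSeq/OMIM/Pfam ingestion and KEGG compound/reaction data are out
of scope, as are incremental updates, network retrieval, community
detection, centrality beyond degree, and weighted-path variants of the
neighbor classification. The schema covers the documented core, not a full
production warehouse's auxiliary speed-up tables.
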