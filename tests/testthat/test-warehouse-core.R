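# Schema emission, WID assignment, batch atomicity, cross-reference
# resolution and reopen behaviour of the relational store.

test_that("emitted DDL is deterministic and executes the published SQL as printed", {
  expect_identical(schema_ddl(), schema_ddl())

  store <- new_store()
  on.exit(wh_disconnect(store))
  wh_insert(store, "protein", data.frame(
    primary_accession = "Q8DR59", accessions = I(list("Q8DR59")),
    name = "PBP", sequence = "MKLV", tax_id = 171101L,
    gene_locus_tags = I(list(character(0)))))
  rows <- run_sql(store, sql_protein_by_accession("Q8DR59"))
  expect_equal(nrow(rows), 1)
  expect_equal(rows$Seq, "MKLV")
})

test_that("the synonym-join SQL finds exactly the human-linked protein on a 3-protein fixture", {
  # hand enumeration: of three proteins only P2 carries tax 9606, whose
  # taxonomy node owns the synonym 'human' -> the join yields exactly 1 row
  store <- new_store()
  on.exit(wh_disconnect(store))
  taxa <- chain_taxa(2)
  taxa$tax_id <- c(1L, 9606L); taxa$parent_tax_id <- c(1L, 1L)
  taxa$synonyms[[2]] <- "human"
  wh_insert(store, "taxonomy", taxa)
  wh_insert(store, "protein", data.frame(
    primary_accession = c("P1", "P2", "P3"),
    accessions = I(list("P1", "P2", "P3")),
    name = "x", sequence = c("AAA", "CCC", "GGG"),
    tax_id = c(1L, 9606L, 1L),
    gene_locus_tags = I(replicate(3, character(0), simplify = FALSE))))
  quiet(resolve_crossrefs(store))
  rows <- run_sql(store, sql_protein_by_taxon_synonym("human"))
  expect_equal(nrow(rows), 1)
  expect_equal(rows$Seq, "CCC")
})

test_that("store creation, reopening and refusal of non-store files", {
  path <- tempfile(fileext = ".db")
  store <- wh_connect(path)
  expect_true(all(wh_counts(store) == 0))
  wh_insert(store, "taxonomy", chain_taxa(3))
  wh_disconnect(store)

  reopened <- wh_connect(path)
  expect_equal(unname(wh_counts(reopened)["taxonomy"]), 3L)
  # counter preserved: next WID continues after the existing ones
  wh_insert(reopened, "drug", data.frame(
    drugbank_id = "DB00001", name = "d", description = "",
    target_accessions = I(list(character(0)))))
  expect_equal(wh_get(reopened, "drug")$wid, 4L)
  wh_disconnect(reopened)

  not_a_store <- tempfile()
  writeLines("just some text, definitely not a database", not_a_store)
  expect_error(wh_connect(not_a_store), "not a bioweave store")
})

test_that("WIDs are unique across kinds and strictly increasing", {
  store <- new_store()
  on.exit(wh_disconnect(store))
  wh_insert(store, "taxonomy", chain_taxa(3))
  wh_insert(store, "drug", data.frame(
    drugbank_id = c("DB1", "DB2"), name = "d", description = "",
    target_accessions = I(replicate(2, character(0), simplify = FALSE))))
  wh_insert(store, "term", data.frame(
    term_id = "GO:1", name = "t", namespace = "bp",
    is_a_parents = I(list(character(0)))))
  wids <- c(wh_get(store, "taxonomy")$wid, wh_get(store, "drug")$wid,
            wh_get(store, "term")$wid)
  expect_equal(sort(wids), 1:6)
  expect_false(anyDuplicated(wids) > 0)
})

test_that("a batch violating an invariant is rejected whole, store unchanged", {
  store <- new_store()
  on.exit(wh_disconnect(store))
  wh_insert(store, "taxonomy", chain_taxa(2))
  ok <- data.frame(gene_id = 1:2, locus_tag = c("a", "b"), symbol = "s",
                   tax_id = 1L, synonyms = I(replicate(2, character(0),
                                                       simplify = FALSE)))
  wh_insert(store, "gene", ok)
  dup <- data.frame(gene_id = c(10L, 2L), locus_tag = c("c", "d"),
                    symbol = "s", tax_id = 1L,
                    synonyms = I(replicate(2, character(0), simplify = FALSE)))
  expect_error(wh_insert(store, "gene", dup), class = "wh_constraint_error")
  expect_equal(unname(wh_counts(store)["gene"]), 2L)
  expect_equal(wh_get(store, "gene")$gene_id, 1:2)
  # empty batch inserts zero
  expect_equal(wh_insert(store, "gene", ok[0, ]), 0L)
})

test_that("taxonomy batches must form a single rooted tree", {
  store <- new_store()
  on.exit(wh_disconnect(store))
  two_roots <- chain_taxa(3)
  two_roots$parent_tax_id[3] <- 3L
  expect_error(wh_insert(store, "taxonomy", two_roots),
               class = "wh_constraint_error")
  missing_parent <- chain_taxa(2)
  missing_parent$parent_tax_id[2] <- 99L
  expect_error(wh_insert(store, "taxonomy", missing_parent),
               class = "wh_constraint_error")
  expect_equal(unname(wh_counts(store)["taxonomy"]), 0L)
})

test_that("resolve_crossrefs links the printed drug-protein facts and counts match a brute-force join", {
  store <- paper_store()
  hets <- linked(store, "drug", "DB00739", "protein")
  expect_setequal(unlist(hets$accessions),
                  c("Q8DR59", "PBP2_STRR6", "PBPA_STRR6"))
  # oracle: recompute the drug-protein link count from the spec tables
  spec <- paper_spec()
  pm <- oracle_primary_map(spec)
  n_oracle <- sum(vapply(spec$drug$target_accessions, function(t)
    length(unique(pm[toupper(t)][!is.na(pm[toupper(t)])])), integer(1)))
  counts <- quiet(resolve_crossrefs(store))
  expect_equal(unname(counts["drug_protein"]), n_oracle)
  # a store with no drugs has zero drug links
  empty <- new_store()
  on.exit(wh_disconnect(empty))
  expect_equal(unname(quiet(resolve_crossrefs(empty))["drug_protein"]), 0L)
})

test_that("after resolution every stored link endpoint exists (referential closure)", {
  store <- loaded_store(random_world(11))
  on.exit(wh_disconnect(store))
  for (tbl in c("Protein_has_Taxonomy", "Protein_has_Gene", "PTT_has_Protein",
                "Drug_has_Protein", "Pathway_has_Protein",
                "Interaction_has_Protein", "Protein_has_UniRefCluster")) {
    links <- DBI::dbGetQuery(store$con, sprintf("SELECT * FROM %s", tbl))
    all_wids <- integer(0)
    for (k in wh_kinds()) all_wids <- c(all_wids, wh_get(store, k)$wid)
    for (col in names(links))
      expect_true(all(links[[col]] %in% all_wids),
                  label = sprintf("%s.%s within stored WIDs", tbl, col))
  }
})
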