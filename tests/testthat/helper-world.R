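# Shared fixtures built in code.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

new_store <- function(path = ":memory:") wh_connect(path)

# A store loaded with a spec through the full write -> parse -> load route.
loaded_store <- function(spec, path = ":memory:") {
  store <- wh_connect(path)
  quiet(load_world(store, spec))
  store
}

# The printed-facts world, loaded once per test run and memoised.
.paper_env <- new.env()
paper_store <- function() {
  if (is.null(.paper_env$store)) {
    .paper_env$spec <- paper_facts()
    .paper_env$store <- loaded_store(.paper_env$spec)
  }
  .paper_env$store
}
paper_spec <- function() {
  if (is.null(.paper_env$spec)) .paper_env$spec <- paper_facts()
  .paper_env$spec
}

# The two published example SQL statements, verbatim.
sql_protein_by_accession <- function(acc = "Q8DR59") {
  sprintf(paste0(
    "select p.seq from Protein p inner join ProteinAccessionNumber a ",
    "on a.Protein_WID = p.WID where a.AccessionNumber = '%s';"), acc)
}
sql_protein_by_taxon_synonym <- function(synonym = "human") {
  sprintf(paste0(
    "select p.seq from Protein p inner join Protein_has_Taxonomy pt ",
    "on pt.Protein_WID = p.WID inner join TaxonomySynonym ts ",
    "on ts.Taxonomy_WID = pt.Taxonomy_WID where ts.Synonym like '%s';"), synonym)
}

run_sql <- function(store, sql) DBI::dbGetQuery(store$con, sql)

# A tiny hand-enumerable taxonomy chain: 1 <- 2 <- ... <- n.
chain_taxa <- function(n) {
  data.frame(tax_id = seq_len(n),
             parent_tax_id = c(1L, seq_len(n - 1L)),
             rank = "no rank",
             scientific_name = sprintf("node %d", seq_len(n)),
             synonyms = I(replicate(n, character(0), simplify = FALSE)))
}
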