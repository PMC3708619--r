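# Text search with composable cross-module constraints.
#
# Matching is case-insensitive substring everywhere ("like '%term%'"
# semantics; an empty term matches every record); `exact = TRUE` switches to
# whole-identifier equality.  Results are ordered by ascending WID for
# reproducibility.

#' Build a search constraint
#'
#' A constraint restricts a search to entities cross-linked to any record of
#' prior result sets.  Only the `"IN"` operator is implemented; the operator
#' list is extensible and the third, opaque slot is accepted and unused.
#'
#' @param operand_sets A result data.frame (e.g. from [search_taxonomy()])
#'   or a list of them.
#' @param operators Character vector of operators, recycled to the operands;
#'   only `"IN"` is supported.
#' @param extra Opaque optional payload, ignored.
#' @return A `wh_constraint` object.
#' @export
wh_constraint <- function(operand_sets, operators = "IN", extra = NULL) {
  if (is.data.frame(operand_sets)) operand_sets <- list(operand_sets)
  operators <- rep_len(operators, length(operand_sets))
  if (!all(operators == "IN"))
    wh_usage_stop("only the \"IN\" constraint operator is implemented")
  structure(list(operand_sets = operand_sets, operators = operators,
                 extra = extra), class = "wh_constraint")
}

wh_like <- function(term) paste0("%", toupper(term), "%")

#' Search taxonomy nodes
#'
#' Matches the scientific name or any synonym, case-insensitively as a
#' substring.  An empty term matches every node.
#'
#' @param store A `wh_store`.
#' @param term Search text.
#' @param exact Match the whole name/synonym instead of a substring.
#' @return Taxonomy records (with `wid`), ordered by WID.
#' @export
search_taxonomy <- function(store, term, exact = FALSE) {
  cmp <- if (exact) "= ?" else "LIKE ?"
  val <- if (exact) toupper(term) else wh_like(term)
  wids <- wh_query(store, sprintf(
    "SELECT DISTINCT t.WID FROM Taxonomy t
     LEFT JOIN TaxonomySynonym s ON s.Taxonomy_WID = t.WID
     WHERE UPPER(t.ScientificName) %s OR UPPER(s.Synonym) %s
     ORDER BY t.WID", cmp, cmp), params = list(val, val))$WID
  wh_get(store, "taxonomy", wids = wids)
}

# Shared matcher for the simpler entity searches.
wh_search_fields <- function(store, kind, fields, term, exact, constraint_sql = NULL,
                             constraint_params = NULL) {
  meta <- .wh_kind_meta[[kind]]
  cmp <- if (exact) "= ?" else "LIKE ?"
  val <- if (exact) toupper(term) else wh_like(term)
  clauses <- vapply(fields, function(f) sprintf("UPPER(%s) %s", f, cmp), character(1))
  sql <- sprintf("SELECT DISTINCT e.WID FROM %s e %s WHERE (%s)%s ORDER BY e.WID",
                 meta$table,
                 attr(fields, "joins") %||% "",
                 paste(clauses, collapse = " OR "),
                 constraint_sql %||% "")
  params <- c(rep(list(val), length(fields)), constraint_params)
  wids <- wh_query(store, sql, params = params)$WID
  wh_get(store, kind, wids = wids)
}

#' Search proteins, optionally under a taxonomy constraint
#'
#' Matches any accession or the protein name.  With an `"IN"` taxonomy
#' constraint the result is restricted to proteins holding a resolved
#' protein-taxonomy link into the constraint set (run
#' [resolve_crossrefs()] first); an empty term under a constraint returns
#' every protein below the constrained taxa.
#'
#' @param store A `wh_store`.
#' @param term Search text.
#' @param constraint Optional [wh_constraint()] over taxonomy results.
#' @param exact Whole-identifier matching.
#' @return Protein records (with `wid`), ordered by WID.
#' @export
search_protein <- function(store, term, constraint = NULL, exact = FALSE) {
  fields <- c("a.AccessionNumber", "e.Name")
  attr(fields, "joins") <- "LEFT JOIN ProteinAccessionNumber a ON a.Protein_WID = e.WID"
  csql <- NULL; cpar <- NULL
  if (!is.null(constraint)) {
    stopifnot(inherits(constraint, "wh_constraint"))
    csql <- ""
    cpar <- list()
    for (set in constraint$operand_sets) {
      if (!"tax_id" %in% names(set))
        wh_usage_stop("protein search constraints must be taxonomy result sets")
      wids <- set$wid %||% integer(0)
      if (length(wids) == 0) { csql <- paste0(csql, " AND 0 = 1"); next }
      csql <- paste0(csql, sprintf(
        " AND e.WID IN (SELECT Protein_WID FROM Protein_has_Taxonomy WHERE Taxonomy_WID IN (%s))",
        paste(rep("?", length(wids)), collapse = ",")))
      cpar <- c(cpar, as.list(as.integer(wids)))
    }
  }
  wh_search_fields(store, "protein", fields, term, exact, csql, cpar)
}

#' Search drugs by name or DrugBank id
#' @inheritParams search_protein
#' @return Drug records ordered by WID.
#' @export
search_drug <- function(store, term, exact = FALSE) {
  wh_search_fields(store, "drug", c("e.Name", "e.DrugBankId"), term, exact)
}

#' Search genes by symbol, locus tag or GeneID text
#' @inheritParams search_protein
#' @return Gene records ordered by WID.
#' @export
search_gene <- function(store, term, exact = FALSE) {
  wh_search_fields(store, "gene",
                   c("e.Symbol", "e.LocusTag", "CAST(e.GeneId AS TEXT)"),
                   term, exact)
}

#' Search pathways by name or KEGG id
#' @inheritParams search_protein
#' @return Pathway records ordered by WID.
#' @export
search_pathway <- function(store, term, exact = FALSE) {
  wh_search_fields(store, "pathway", c("e.Name", "e.KeggId"), term, exact)
}

# Link-table routes for linked(); symmetric.
.wh_link_routes <- list(
  protein_taxonomy = c(table = "Protein_has_Taxonomy", protein = "Protein_WID",
                       taxonomy = "Taxonomy_WID"),
  protein_gene = c(table = "Protein_has_Gene", protein = "Protein_WID",
                   gene = "Gene_WID"),
  ptt_protein = c(table = "PTT_has_Protein", ptt = "PTT_WID",
                  protein = "Protein_WID"),
  drug_protein = c(table = "Drug_has_Protein", drug = "Drug_WID",
                   protein = "Protein_WID"),
  pathway_protein = c(table = "Pathway_has_Protein", pathway = "Pathway_WID",
                      protein = "Protein_WID"),
  interaction_protein = c(table = "Interaction_has_Protein",
                          interaction = "Interaction_WID",
                          protein = "Protein_WID"),
  protein_uniref = c(table = "Protein_has_UniRefCluster", protein = "Protein_WID",
                     uniref = "UniRefCluster_WID"),
  enzyme_protein = c(table = "Enzyme_has_Protein", enzyme = "Enzyme_WID",
                     protein = "Protein_WID")
)

#' Entities cross-linked to a given entity
#'
#' Follows a resolved cross-reference link table between two entity kinds
#' (in either direction): protein-taxonomy, protein-gene, ptt-protein,
#' drug-protein, pathway-protein, interaction-protein, protein-uniref,
#' enzyme-protein.  Run [resolve_crossrefs()] after loading.
#'
#' @param store A `wh_store`.
#' @param kind Kind of the query entity.
#' @param key Its natural key (tax_id, accession, DrugBank id, KEGG id,
#'   locus tag / GeneID, cluster id, EC number, term id) or, as a
#'   convenience, a single-row result from a `search_*` call.
#' @param target Kind of the linked entities wanted.
#' @return Records of `target` kind, ordered by WID.
#' @export
linked <- function(store, kind, key, target) {
  kind <- match.arg(kind, wh_kinds())
  target <- match.arg(target, wh_kinds())
  route <- NULL
  for (r in .wh_link_routes) {
    if (kind %in% names(r) && target %in% names(r) && kind != target) {
      route <- r
      break
    }
  }
  if (is.null(route))
    wh_usage_stop(sprintf("no cross-reference link between %s and %s", kind, target))
  if (is.data.frame(key)) {
    wids <- key$wid
  } else {
    wids <- wh_lookup(store, kind, key)$wid
  }
  if (length(wids) == 0) return(wh_get(store, target, wids = integer(0)))
  out <- wh_query(store, sprintf(
    "SELECT DISTINCT %s AS W FROM %s WHERE %s IN (%s) ORDER BY W",
    route[[target]], route[["table"]], route[[kind]],
    paste(rep("?", length(wids)), collapse = ",")),
    params = as.list(as.integer(wids)))$W
  wh_get(store, target, wids = out)
}
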