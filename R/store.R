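# Warehouse store: an embedded relational database accessed over DBI.

.wh_kind_meta <- list(
  taxonomy = list(
    table = "Taxonomy",
    cols = c(tax_id = "TaxId", parent_tax_id = "ParentTaxId", rank = "Rank",
             scientific_name = "ScientificName"),
    side = list(synonyms = list(table = "TaxonomySynonym", fk = "Taxonomy_WID",
                                col = "Synonym"))
  ),
  gene = list(
    table = "Gene",
    cols = c(gene_id = "GeneId", locus_tag = "LocusTag", symbol = "Symbol",
             tax_id = "TaxId"),
    side = list(synonyms = list(table = "GeneSynonym", fk = "Gene_WID",
                                col = "Synonym"))
  ),
  ptt = list(
    table = "PTT",
    cols = c(replicon_accession = "RepliconAccession", start_bp = "StartBp",
             end_bp = "EndBp", strand = "Strand", pid = "Pid",
             gene_symbol = "GeneSymbol", locus_tag = "LocusTag",
             product = "Product"),
    side = list()
  ),
  protein = list(
    table = "Protein",
    cols = c(name = "Name", sequence = "Seq", tax_id = "TaxId"),
    side = list(
      accessions = list(table = "ProteinAccessionNumber", fk = "Protein_WID",
                        col = "AccessionNumber"),
      gene_locus_tags = list(table = "ProteinLocusTag", fk = "Protein_WID",
                             col = "LocusTag"))
  ),
  interaction = list(
    table = "Interaction",
    cols = c(source_dataset = "SourceDataset", interactor_a = "InteractorA",
             interactor_b = "InteractorB", detection_method = "DetectionMethod",
             pubmed_id = "PubmedId"),
    side = list()
  ),
  uniref = list(
    table = "UniRefCluster",
    cols = c(cluster_id = "ClusterId",
             representative_accession = "RepresentativeAccession"),
    side = list(member_accessions = list(table = "UniRefClusterMember",
                                         fk = "UniRefCluster_WID",
                                         col = "AccessionNumber"))
  ),
  drug = list(
    table = "Drug",
    cols = c(drugbank_id = "DrugBankId", name = "Name",
             description = "Description"),
    side = list(target_accessions = list(table = "DrugTargetAccession",
                                         fk = "Drug_WID",
                                         col = "AccessionNumber"))
  ),
  pathway = list(
    table = "Pathway",
    cols = c(kegg_id = "KeggId", name = "Name",
             organism_tax_id = "OrganismTaxId", map_number = "MapNumber"),
    side = list(member_accessions = list(table = "PathwayMemberAccession",
                                         fk = "Pathway_WID",
                                         col = "AccessionNumber"))
  ),
  enzyme = list(
    table = "Enzyme",
    cols = c(ec_number = "ECNumber"),
    side = list(
      names = list(table = "EnzymeName", fk = "Enzyme_WID", col = "Name"),
      protein_accessions = list(table = "EnzymeProteinAccession",
                                fk = "Enzyme_WID", col = "AccessionNumber"))
  ),
  term = list(
    table = "OntologyTerm",
    cols = c(term_id = "TermId", name = "Name", namespace = "Namespace"),
    side = list(is_a_parents = list(table = "OntologyTermParent",
                                    fk = "OntologyTerm_WID",
                                    col = "ParentTermId"))
  )
)

#' Open (or create) a warehouse store
#'
#' A store is an embedded SQLite database carrying the schema emitted by
#' [schema_ddl()].  A fresh path is initialized with the schema and a WID
#' counter at zero; an existing store is reopened with its counter preserved;
#' a file that is not a warehouse store is refused.
#'
#' @param path Database file path, or `":memory:"` for a transient store.
#' @return A `wh_store` handle.
#' @export
wh_connect <- function(path) {
  fresh <- identical(path, ":memory:") || !file.exists(path)
  if (!fresh && file.exists(path) && file.size(path) == 0) fresh <- TRUE
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path, synchronous = NULL),
                  error = function(e) stop("cannot open store at ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  store <- structure(list(con = con, path = path), class = "wh_store")
  if (fresh) {
    for (stmt in wh_ddl_statements()) DBI::dbExecute(con, stmt)
    DBI::dbExecute(con, "INSERT INTO WIDSequence (LastWID) VALUES (0)")
  } else {
    ok <- tryCatch("WIDSequence" %in% DBI::dbListTables(con),
                   error = function(e) FALSE)
    if (!ok) {
      DBI::dbDisconnect(con)
      stop(path, " exists but is not a bioweave store", call. = FALSE)
    }
  }
  store
}

#' Close a store handle
#' @param store A `wh_store`.
#' @export
wh_disconnect <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(NULL)
}

#' @export
print.wh_store <- function(x, ...) {
  cat("<bioweave warehouse store> ", x$path, "\n", sep = "")
  counts <- wh_counts(x)
  cat(paste(sprintf("  %-12s %d", names(counts), counts), collapse = "\n"), "\n")
  invisible(x)
}

wh_query <- function(store, sql, params = NULL) {
  DBI::dbGetQuery(store$con, sql, params = params)
}

#' Entity counts per kind
#' @param store A `wh_store`.
#' @return Named integer vector over `wh_kinds()`.
#' @export
wh_counts <- function(store) {
  vapply(wh_kinds(), function(k) {
    as.integer(wh_query(store, sprintf("SELECT COUNT(*) AS n FROM %s",
                                       .wh_kind_meta[[k]]$table))$n)
  }, integer(1))
}

wh_last_wid <- function(store) {
  as.integer(wh_query(store, "SELECT LastWID FROM WIDSequence")$LastWID)
}

# Cross-batch/store uniqueness and structural checks before inserting.
wh_validate_against_store <- function(store, kind, data) {
  fail <- wh_constraint_stop
  has <- function(sql, vals) {
    if (length(vals) == 0) return(character(0))
    ph <- paste(rep("?", length(vals)), collapse = ",")
    wh_query(store, sprintf(sql, ph), params = as.list(vals))[[1]]
  }
  switch(kind,
    taxonomy = {
      clash <- has("SELECT TaxId FROM Taxonomy WHERE TaxId IN (%s)", data$tax_id)
      if (length(clash)) fail(sprintf("tax_id already stored: %s", clash[1]))
      stored <- wh_query(store, "SELECT TaxId, ParentTaxId FROM Taxonomy")
      all_ids <- c(stored$TaxId, data$tax_id)
      if (length(all_ids) == 0) return(invisible(TRUE))
      parent <- stats::setNames(c(stored$ParentTaxId, data$parent_tax_id), all_ids)
      roots <- all_ids[parent[as.character(all_ids)] == all_ids]
      if (length(roots) != 1)
        fail(sprintf("taxonomy must have exactly one root (found %d)", length(roots)))
      if (!all(parent %in% all_ids))
        fail("parent_tax_id must refer to a loaded node")
      # cycle check: every node must reach the root
      for (id in all_ids) {
        seen <- integer(0); cur <- id
        while (parent[as.character(cur)] != cur) {
          if (cur %in% seen) fail(sprintf("taxonomy cycle at tax_id %s", cur))
          seen <- c(seen, cur)
          cur <- parent[as.character(cur)]
        }
      }
    },
    gene = {
      clash <- has("SELECT GeneId FROM Gene WHERE GeneId IN (%s)", data$gene_id)
      if (length(clash)) fail(sprintf("gene_id already stored: %s", clash[1]))
      key <- data[nzchar(data$locus_tag %||% "") & !is.na(data$locus_tag), ]
      if (nrow(key)) {
        stored <- wh_query(store, "SELECT TaxId, UPPER(LocusTag) AS L FROM Gene WHERE LocusTag IS NOT NULL")
        k1 <- paste(key$tax_id, toupper(key$locus_tag))
        if (any(k1 %in% paste(stored$TaxId, stored$L)))
          fail("locus_tag already stored for this tax_id")
      }
    },
    ptt = {
      stored <- wh_query(store, "SELECT UPPER(RepliconAccession) AS R, UPPER(LocusTag) AS L FROM PTT")
      if (nrow(stored) && any(paste(toupper(data$replicon_accession), toupper(data$locus_tag))
                              %in% paste(stored$R, stored$L)))
        fail("(replicon, locus_tag) already stored")
    },
    protein = {
      clash <- has("SELECT AccessionNumber FROM ProteinAccessionNumber WHERE UPPER(AccessionNumber) IN (%s)",
                   toupper(unlist(data$accessions)))
      if (length(clash)) fail(sprintf("accession already stored: %s", clash[1]))
    },
    interaction = {
      pair <- t(apply(cbind(toupper(data$interactor_a), toupper(data$interactor_b)), 1, sort))
      key <- paste(data$source_dataset, pair[, 1], pair[, 2],
                   data$detection_method, data$pubmed_id)
      if (anyDuplicated(key)) fail("duplicate interaction record in batch")
      stored <- wh_query(store,
        "SELECT SourceDataset, UPPER(InteractorA) AS A, UPPER(InteractorB) AS B,
                DetectionMethod, PubmedId FROM Interaction")
      if (nrow(stored)) {
        sp <- t(apply(cbind(stored$A, stored$B), 1, sort))
        skey <- paste(stored$SourceDataset, sp[, 1], sp[, 2],
                      stored$DetectionMethod, stored$PubmedId)
        if (any(key %in% skey)) fail("interaction record already stored")
      }
    },
    uniref = {
      clash <- has("SELECT ClusterId FROM UniRefCluster WHERE UPPER(ClusterId) IN (%s)",
                   toupper(data$cluster_id))
      if (length(clash)) fail(sprintf("cluster_id already stored: %s", clash[1]))
      clash <- has("SELECT AccessionNumber FROM UniRefClusterMember WHERE UPPER(AccessionNumber) IN (%s)",
                   toupper(unlist(data$member_accessions)))
      if (length(clash)) fail(sprintf("accession already clustered: %s", clash[1]))
    },
    drug = {
      clash <- has("SELECT DrugBankId FROM Drug WHERE UPPER(DrugBankId) IN (%s)",
                   toupper(data$drugbank_id))
      if (length(clash)) fail(sprintf("drugbank_id already stored: %s", clash[1]))
    },
    pathway = {
      clash <- has("SELECT KeggId FROM Pathway WHERE UPPER(KeggId) IN (%s)",
                   toupper(data$kegg_id))
      if (length(clash)) fail(sprintf("kegg_id already stored: %s", clash[1]))
    },
    enzyme = {
      clash <- has("SELECT ECNumber FROM Enzyme WHERE ECNumber IN (%s)", data$ec_number)
      if (length(clash)) fail(sprintf("ec_number already stored: %s", clash[1]))
    },
    term = {
      clash <- has("SELECT TermId FROM OntologyTerm WHERE UPPER(TermId) IN (%s)",
                   toupper(data$term_id))
      if (length(clash)) fail(sprintf("term_id already stored: %s", clash[1]))
      combined <- c(wh_query(store, "SELECT TermId FROM OntologyTerm")$TermId, data$term_id)
      dangling <- setdiff(toupper(unlist(data$is_a_parents)), toupper(combined))
      if (length(dangling))
        message("ontology: ", length(dangling), " dangling is_a parent(s) kept as-is")
    }
  )
  invisible(TRUE)
}

#' Insert a batch of records
#'
#' Persists a record set, assigning each record a fresh WID from the store's
#' single strictly increasing counter.  The batch is atomic: any invariant
#' violation (including a natural-key clash with already-stored records)
#' rejects the whole batch and leaves the store unchanged.
#'
#' @param store A `wh_store`.
#' @param kind Entity kind, one of `wh_kinds()`; omit when `data` came from
#'   [wh_records()].
#' @param data Record data.frame.
#' @return Number of WIDs assigned, invisibly.
#' @export
wh_insert <- function(store, kind, data) {
  if (missing(data)) { data <- kind; kind <- attr(data, "wh_kind") }
  data <- wh_records(kind, data)
  n <- nrow(data)
  DBI::dbWithTransaction(store$con, {
    wh_validate_against_store(store, kind, data)
    if (n > 0) {
      meta <- .wh_kind_meta[[kind]]
      last <- wh_last_wid(store)
      wids <- last + seq_len(n)
      DBI::dbExecute(store$con, "UPDATE WIDSequence SET LastWID = ?",
                     params = list(last + n))
      sqlcols <- unname(meta$cols)
      sql <- sprintf("INSERT INTO %s (WID, %s) VALUES (?%s)", meta$table,
                     paste(sqlcols, collapse = ", "),
                     strrep(", ?", length(sqlcols)))
      params <- c(list(wids), lapply(names(meta$cols), function(cn) data[[cn]]))
      DBI::dbExecute(store$con, sql, params = unname(params))
      for (fld in names(meta$side)) {
        side <- meta$side[[fld]]
        vals <- data[[fld]]
        lens <- lengths(vals)
        if (sum(lens) == 0) next
        DBI::dbExecute(store$con,
          sprintf("INSERT INTO %s (%s, %s, Position) VALUES (?, ?, ?)",
                  side$table, side$fk, side$col),
          params = list(rep(wids, lens), unlist(vals),
                        unlist(lapply(lens, seq_len)) - 1L))
      }
    }
  })
  invisible(n)
}

#' Retrieve stored records of one kind
#'
#' Reassembles full records (multi-valued fields as list-columns) from the
#' relational tables, ordered by WID.
#'
#' @param store A `wh_store`.
#' @param kind Entity kind.
#' @param wids Optional WID filter.
#' @return Data.frame with a leading `wid` column.
#' @export
wh_get <- function(store, kind, wids = NULL) {
  kind <- match.arg(kind, wh_kinds())
  meta <- .wh_kind_meta[[kind]]
  where <- ""
  params <- NULL
  if (!is.null(wids)) {
    if (length(wids) == 0) {
      out <- wh_empty_records(kind)
      out <- cbind(wid = integer(0), out)
      return(out)
    }
    where <- sprintf(" WHERE WID IN (%s)", paste(rep("?", length(wids)), collapse = ","))
    params <- as.list(as.integer(wids))
  }
  main <- wh_query(store, sprintf("SELECT WID, %s FROM %s%s ORDER BY WID",
                                  paste(sprintf("%s AS %s", unname(meta$cols), names(meta$cols)),
                                        collapse = ", "),
                                  meta$table, where), params = params)
  out <- data.frame(wid = as.integer(main$WID))
  for (cn in names(meta$cols)) {
    out[[cn]] <- if (cn %in% .wh_int_columns[[kind]]) as.integer(main[[cn]])
                 else as.character(main[[cn]])
  }
  for (fld in names(meta$side)) {
    side <- meta$side[[fld]]
    rows <- wh_query(store, sprintf(
      "SELECT %s AS fk, %s AS val FROM %s ORDER BY fk, Position",
      side$fk, side$col, side$table))
    sp <- split(rows$val, factor(rows$fk, levels = out$wid))
    out[[fld]] <- lapply(unname(sp), as.character)
  }
  if (kind == "protein") {
    out$primary_accession <- vapply(out$accessions, function(a)
      if (length(a)) a[[1]] else NA_character_, character(1))
  }
  cols <- c("wid", .wh_kind_columns[[kind]])
  out[, cols, drop = FALSE]
}

#' Resolve cross-references between loaded entities
#'
#' Rebuilds every `Entity_has_Other` link table by joining natural
#' identifiers case-insensitively: protein-taxonomy via tax_id,
#' protein-gene via locus_tag (and matching tax_id where both are known),
#' PTT-protein via the PID column, drug-protein and pathway-protein and
#' enzyme-protein via target/member accessions, interaction-protein via the
#' interactor accessions, and protein-UniRef via cluster membership.
#' References that do not resolve to a loaded entity are counted and
#' reported as messages, never fabricated.
#'
#' @param store A `wh_store`.
#' @return Named integer vector of link counts per link kind, with an
#'   `unresolved` attribute counting dangling references per link kind.
#' @export
resolve_crossrefs <- function(store) {
  con <- store$con
  specs <- list(
    protein_taxonomy = list(
      fill = "INSERT INTO Protein_has_Taxonomy (Protein_WID, Taxonomy_WID)
              SELECT p.WID, t.WID FROM Protein p
              JOIN Taxonomy t ON t.TaxId = p.TaxId",
      dangling = "SELECT COUNT(*) FROM Protein p WHERE p.TaxId IS NOT NULL
                  AND NOT EXISTS (SELECT 1 FROM Taxonomy t WHERE t.TaxId = p.TaxId)"),
    protein_gene = list(
      fill = "INSERT INTO Protein_has_Gene (Protein_WID, Gene_WID)
              SELECT DISTINCT pl.Protein_WID, g.WID
              FROM ProteinLocusTag pl
              JOIN Protein p ON p.WID = pl.Protein_WID
              JOIN Gene g ON UPPER(g.LocusTag) = UPPER(pl.LocusTag)
                         AND (g.TaxId IS NULL OR p.TaxId IS NULL OR g.TaxId = p.TaxId)",
      dangling = "SELECT COUNT(*) FROM ProteinLocusTag pl
                  WHERE NOT EXISTS (SELECT 1 FROM Gene g
                    WHERE UPPER(g.LocusTag) = UPPER(pl.LocusTag))"),
    ptt_protein = list(
      fill = "INSERT INTO PTT_has_Protein (PTT_WID, Protein_WID)
              SELECT DISTINCT pt.WID, a.Protein_WID FROM PTT pt
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(pt.Pid)",
      dangling = "SELECT COUNT(*) FROM PTT pt WHERE pt.Pid IS NOT NULL
                  AND NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                    WHERE UPPER(a.AccessionNumber) = UPPER(pt.Pid))"),
    drug_protein = list(
      fill = "INSERT INTO Drug_has_Protein (Drug_WID, Protein_WID)
              SELECT DISTINCT dt.Drug_WID, a.Protein_WID FROM DrugTargetAccession dt
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(dt.AccessionNumber)",
      dangling = "SELECT COUNT(*) FROM DrugTargetAccession dt
                  WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                    WHERE UPPER(a.AccessionNumber) = UPPER(dt.AccessionNumber))"),
    pathway_protein = list(
      fill = "INSERT INTO Pathway_has_Protein (Pathway_WID, Protein_WID)
              SELECT DISTINCT pm.Pathway_WID, a.Protein_WID FROM PathwayMemberAccession pm
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(pm.AccessionNumber)",
      dangling = "SELECT COUNT(*) FROM PathwayMemberAccession pm
                  WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                    WHERE UPPER(a.AccessionNumber) = UPPER(pm.AccessionNumber))"),
    interaction_protein = list(
      fill = "INSERT INTO Interaction_has_Protein (Interaction_WID, Protein_WID)
              SELECT DISTINCT i.WID, a.Protein_WID FROM Interaction i
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(i.InteractorA)
                OR UPPER(a.AccessionNumber) = UPPER(i.InteractorB)",
      dangling = "SELECT (SELECT COUNT(*) FROM Interaction i
                   WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                     WHERE UPPER(a.AccessionNumber) = UPPER(i.InteractorA)))
                + (SELECT COUNT(*) FROM Interaction i
                   WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                     WHERE UPPER(a.AccessionNumber) = UPPER(i.InteractorB)))"),
    protein_uniref = list(
      fill = "INSERT INTO Protein_has_UniRefCluster (Protein_WID, UniRefCluster_WID)
              SELECT DISTINCT a.Protein_WID, m.UniRefCluster_WID FROM UniRefClusterMember m
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(m.AccessionNumber)",
      dangling = "SELECT COUNT(*) FROM UniRefClusterMember m
                  WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                    WHERE UPPER(a.AccessionNumber) = UPPER(m.AccessionNumber))"),
    enzyme_protein = list(
      fill = "INSERT INTO Enzyme_has_Protein (Enzyme_WID, Protein_WID)
              SELECT DISTINCT ep.Enzyme_WID, a.Protein_WID FROM EnzymeProteinAccession ep
              JOIN ProteinAccessionNumber a
                ON UPPER(a.AccessionNumber) = UPPER(ep.AccessionNumber)",
      dangling = "SELECT COUNT(*) FROM EnzymeProteinAccession ep
                  WHERE NOT EXISTS (SELECT 1 FROM ProteinAccessionNumber a
                    WHERE UPPER(a.AccessionNumber) = UPPER(ep.AccessionNumber))")
  )
  link_tables <- c(protein_taxonomy = "Protein_has_Taxonomy",
                   protein_gene = "Protein_has_Gene",
                   ptt_protein = "PTT_has_Protein",
                   drug_protein = "Drug_has_Protein",
                   pathway_protein = "Pathway_has_Protein",
                   interaction_protein = "Interaction_has_Protein",
                   protein_uniref = "Protein_has_UniRefCluster",
                   enzyme_protein = "Enzyme_has_Protein")
  counts <- integer(0)
  unresolved <- integer(0)
  DBI::dbWithTransaction(con, {
    for (lk in names(specs)) {
      DBI::dbExecute(con, sprintf("DELETE FROM %s", link_tables[[lk]]))
      DBI::dbExecute(con, specs[[lk]]$fill)
      counts[lk] <- as.integer(DBI::dbGetQuery(
        con, sprintf("SELECT COUNT(*) AS n FROM %s", link_tables[[lk]]))$n)
      unresolved[lk] <- as.integer(DBI::dbGetQuery(con, specs[[lk]]$dangling)[[1]])
    }
  })
  dangling_total <- sum(unresolved)
  if (dangling_total > 0)
    message("resolve_crossrefs: ", dangling_total,
            " unresolved reference(s) skipped (",
            paste(sprintf("%s=%d", names(unresolved)[unresolved > 0],
                          unresolved[unresolved > 0]), collapse = ", "), ")")
  structure(counts, unresolved = unresolved)
}

# Look up entity rows by natural key (case-insensitive). Returns wh_get rows.
wh_lookup <- function(store, kind, key) {
  kind <- match.arg(kind, wh_kinds())
  key_chr <- toupper(as.character(key))
  wids <- switch(kind,
    taxonomy = wh_query(store, "SELECT WID FROM Taxonomy WHERE TaxId = ?",
                        params = list(as.integer(key)))$WID,
    gene = {
      if (grepl("^[0-9]+$", key_chr))
        wh_query(store, "SELECT WID FROM Gene WHERE GeneId = ?",
                 params = list(as.integer(key)))$WID
      else
        wh_query(store, "SELECT WID FROM Gene WHERE UPPER(LocusTag) = ?",
                 params = list(key_chr))$WID
    },
    protein = wh_query(store,
      "SELECT DISTINCT Protein_WID FROM ProteinAccessionNumber WHERE UPPER(AccessionNumber) = ?",
      params = list(key_chr))$Protein_WID,
    drug = wh_query(store, "SELECT WID FROM Drug WHERE UPPER(DrugBankId) = ?",
                    params = list(key_chr))$WID,
    pathway = wh_query(store, "SELECT WID FROM Pathway WHERE UPPER(KeggId) = ?",
                       params = list(key_chr))$WID,
    uniref = wh_query(store, "SELECT WID FROM UniRefCluster WHERE UPPER(ClusterId) = ?",
                      params = list(key_chr))$WID,
    enzyme = wh_query(store, "SELECT WID FROM Enzyme WHERE ECNumber = ?",
                      params = list(as.character(key)))$WID,
    term = wh_query(store, "SELECT WID FROM OntologyTerm WHERE UPPER(TermId) = ?",
                    params = list(key_chr))$WID,
    ptt = wh_query(store, "SELECT WID FROM PTT WHERE UPPER(LocusTag) = ?",
                   params = list(key_chr))$WID,
    interaction = stop("interactions have no natural key lookup")
  )
  wh_get(store, kind, wids = wids)
}
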