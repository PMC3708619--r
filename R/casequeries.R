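# Multi-database worked queries composed from search + graphs:
# drug targets in a chromosomal neighborhood, the same scan expanded over
# the orthologs of a gene within a taxonomic subtree, and genomic regions
# dense in drug-target genes.

# Sorted PTT frame of one replicon with a stable order: start, end, locus.
wh_replicon_rows <- function(store, replicon) {
  rows <- wh_query(store,
    "SELECT WID, RepliconAccession, StartBp, EndBp, Strand, Pid, GeneSymbol, LocusTag
     FROM PTT WHERE UPPER(RepliconAccession) = UPPER(?)
     ORDER BY StartBp, EndBp, LocusTag", params = list(replicon))
  rows
}

# DrugBank ids targeting the protein linked to a PTT row; character(0) if none.
wh_ptt_drugs <- function(store, ptt_wid) {
  wh_query(store,
    "SELECT DISTINCT d.DrugBankId AS id FROM PTT_has_Protein pp
     JOIN Drug_has_Protein dp ON dp.Protein_WID = pp.Protein_WID
     JOIN Drug d ON d.WID = dp.Drug_WID
     WHERE pp.PTT_WID = ? ORDER BY d.DrugBankId", params = list(ptt_wid))$id
}

wh_empty_hits <- function() {
  data.frame(gene_id = integer(0), locus_tag = character(0),
             protein_accession = character(0),
             drugs = I(list()), offset = integer(0))[, , drop = FALSE]
}

#' Drug-target genes in a chromosomal neighborhood
#'
#' Orders the query gene's replicon by start coordinate, takes the `k`
#' entries on each side of the gene (gene-rank offsets, truncated at the
#' replicon ends; `k = Inf` for the whole replicon), maps each entry's PID
#' to its protein and that protein's drugs, and returns the entries with at
#' least one drug -- the query gene included if it qualifies.
#'
#' @param store A `wh_store` with resolved cross-references.
#' @param gene A locus tag or NCBI GeneID; the gene must have a PTT entry.
#' @param k Window half-width in genes.
#' @return Data.frame of hits: `gene_id`, `locus_tag`, `protein_accession`,
#'   `drugs` (list-column of DrugBank ids), `offset` (signed gene-rank
#'   distance from the query gene).
#' @export
neighborhood_drug_targets <- function(store, gene, k = 10) {
  grec <- wh_lookup(store, "gene", gene)
  locus <- if (nrow(grec) > 0) grec$locus_tag[1] else as.character(gene)
  prow <- wh_query(store,
    "SELECT WID, RepliconAccession FROM PTT WHERE UPPER(LocusTag) = UPPER(?)",
    params = list(locus))
  if (nrow(prow) == 0)
    wh_usage_stop(sprintf("gene %s has no PTT entry", gene))
  rows <- wh_replicon_rows(store, prow$RepliconAccession[1])
  idx <- match(prow$WID[1], rows$WID)
  lo <- if (is.finite(k)) max(1L, idx - as.integer(k)) else 1L
  hi <- if (is.finite(k)) min(nrow(rows), idx + as.integer(k)) else nrow(rows)
  win <- rows[lo:hi, , drop = FALSE]
  hits <- wh_empty_hits()
  for (i in seq_len(nrow(win))) {
    drugs <- wh_ptt_drugs(store, win$WID[i])
    if (length(drugs) == 0) next
    acc <- wh_query(store,
      "SELECT a.AccessionNumber AS acc FROM PTT_has_Protein pp
       JOIN ProteinAccessionNumber a ON a.Protein_WID = pp.Protein_WID AND a.Position = 0
       WHERE pp.PTT_WID = ?", params = list(win$WID[i]))$acc
    g <- wh_query(store,
      "SELECT GeneId FROM Gene WHERE UPPER(LocusTag) = UPPER(?)",
      params = list(win$LocusTag[i]))$GeneId
    hits <- rbind(hits, data.frame(
      gene_id = if (length(g)) as.integer(g[1]) else NA_integer_,
      locus_tag = win$LocusTag[i],
      protein_accession = if (length(acc)) acc[1] else NA_character_,
      drugs = I(list(drugs)),
      offset = (lo + i - 1L) - idx))
  }
  rownames(hits) <- NULL
  hits
}

#' Ortholog-expanded neighborhood drug-target scan
#'
#' Treats shared UniRef cluster membership as the orthology proxy: the
#' query gene's protein is mapped to its cluster, the cluster members whose
#' tax id lies in the taxonomy subtree below `root_tax_id` are the
#' orthologs, and [neighborhood_drug_targets()] is run around each
#' ortholog's gene.  Hits are unioned and deduplicated by gene id.
#'
#' @param store A `wh_store` with resolved cross-references.
#' @param locus_tag The query gene.
#' @param root_tax_id Root of the taxonomic group to scan.
#' @param k Window half-width in genes.
#' @return Hit data.frame as in [neighborhood_drug_targets()] plus
#'   `tax_id` and `organism` of the genome each hit lies on; empty (with a
#'   warning) when the query protein is in no cluster.
#' @export
ortholog_neighborhood_scan <- function(store, locus_tag, root_tax_id, k = 10) {
  subtree <- wh_subtree_taxids(store, root_tax_id)
  grec <- wh_lookup(store, "gene", locus_tag)
  if (nrow(grec) == 0) wh_usage_stop(sprintf("unknown gene %s", locus_tag))
  prots <- linked(store, "gene", grec[1, , drop = FALSE], "protein")
  empty <- cbind(wh_empty_hits(),
                 data.frame(tax_id = integer(0), organism = character(0)))
  if (nrow(prots) == 0) {
    warning("gene ", locus_tag, " has no linked protein")
    return(empty)
  }
  clusters <- linked(store, "protein", prots$primary_accession[1], "uniref")
  if (nrow(clusters) == 0) {
    warning("protein ", prots$primary_accession[1], " is in no UniRef cluster")
    return(empty)
  }
  members <- linked(store, "uniref", clusters$cluster_id[1], "protein")
  members <- members[members$tax_id %in% subtree, , drop = FALSE]
  out <- empty
  for (i in seq_len(nrow(members))) {
    genes <- linked(store, "protein", members$primary_accession[i], "gene")
    for (j in seq_len(nrow(genes))) {
      hits <- tryCatch(
        neighborhood_drug_targets(store, genes$locus_tag[j], k = k),
        wh_usage_error = function(e) wh_empty_hits())
      if (nrow(hits) == 0) next
      org <- wh_query(store, "SELECT ScientificName FROM Taxonomy WHERE TaxId = ?",
                      params = list(members$tax_id[i]))$ScientificName
      hits$tax_id <- members$tax_id[i]
      hits$organism <- if (length(org)) org[1] else NA_character_
      out <- rbind(out, hits)
    }
  }
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a taxonomic group for drug-target-dense chromosomal regions
#'
#' For every replicon of every organism in the subtree below
#' `root_tax_id`, the drug-target genes (PTT entries whose protein has at
#' least one drug) are sorted by start coordinate and every maximal run of
#' at least `min_targets` target genes spanning at most `max_len_bp`
#' (1-based inclusive, `max(end) - min(start) + 1`) is reported; windows
#' contained in a larger reported window are dropped.
#'
#' @param store A `wh_store` with resolved cross-references.
#' @param root_tax_id Root of the taxonomic group.
#' @param max_len_bp Maximum region span in base pairs.
#' @param min_targets Minimum number of target genes per region.
#' @return Data.frame of hits: `replicon_accession`, `organism`, `tax_id`,
#'   `start_bp`, `end_bp`, `span_bp`, `gene_ids` (list-column, in
#'   coordinate order), `locus_tags` (list-column).
#' @export
region_scan <- function(store, root_tax_id, max_len_bp = 5000, min_targets = 2) {
  subtree <- wh_subtree_taxids(store, root_tax_id)
  replicons <- wh_query(store,
    "SELECT DISTINCT RepliconAccession AS r FROM PTT ORDER BY r")$r
  out <- data.frame(replicon_accession = character(0), organism = character(0),
                    tax_id = integer(0), start_bp = integer(0),
                    end_bp = integer(0), span_bp = integer(0),
                    gene_ids = I(list()), locus_tags = I(list()))
  for (rep_acc in replicons) {
    rows <- wh_replicon_rows(store, rep_acc)
    # organism of the replicon: the tax id of the genes its loci belong to
    taxs <- wh_query(store, sprintf(
      "SELECT DISTINCT g.TaxId AS tax FROM Gene g WHERE UPPER(g.LocusTag) IN (%s)",
      paste(rep("?", nrow(rows)), collapse = ",")),
      params = as.list(toupper(rows$LocusTag)))$tax
    taxs <- taxs[!is.na(taxs)]
    tax <- if (length(taxs)) taxs[1] else NA_integer_
    if (is.na(tax) || !tax %in% subtree) next
    is_target <- vapply(rows$WID, function(w) length(wh_ptt_drugs(store, w)) > 0,
                        logical(1))
    tg <- rows[is_target, , drop = FALSE]
    if (nrow(tg) < min_targets) next
    tg <- tg[order(tg$StartBp, tg$EndBp), , drop = FALSE]
    n <- nrow(tg)
    reach <- integer(n)
    for (i in seq_len(n)) {
      maxend <- tg$EndBp[i]
      j <- i
      while (j < n) {
        cand <- max(maxend, tg$EndBp[j + 1])
        if (cand - tg$StartBp[i] + 1 > max_len_bp) break
        j <- j + 1
        maxend <- cand
      }
      reach[i] <- j
    }
    best <- -1L
    for (i in seq_len(n)) {
      j <- reach[i]
      if (j - i + 1 < min_targets) next
      if (j <= best) next   # contained in an earlier window
      best <- j
      span_end <- max(tg$EndBp[i:j])
      org <- wh_query(store, "SELECT ScientificName FROM Taxonomy WHERE TaxId = ?",
                      params = list(tax))$ScientificName
      gids <- wh_query(store, sprintf(
        "SELECT GeneId, LocusTag FROM Gene WHERE UPPER(LocusTag) IN (%s)",
        paste(rep("?", j - i + 1), collapse = ",")),
        params = as.list(toupper(tg$LocusTag[i:j])))
      ord <- match(toupper(gids$LocusTag), toupper(tg$LocusTag[i:j]))
      gids <- gids[order(ord), , drop = FALSE]
      out <- rbind(out, data.frame(
        replicon_accession = rep_acc,
        organism = if (length(org)) org[1] else NA_character_,
        tax_id = as.integer(tax),
        start_bp = tg$StartBp[i], end_bp = span_end,
        span_bp = span_end - tg$StartBp[i] + 1L,
        gene_ids = I(list(as.integer(gids$GeneId))),
        locus_tags = I(list(tg$LocusTag[i:j]))))
    }
  }
  rownames(out) <- NULL
  out
}

#' Organisms sharing a drug's pathways at map level
#'
#' Collects the KEGG map numbers of the pathways containing the query
#' drug's targets, then every pathway with one of those map numbers that is
#' itself targeted by some drug, and returns those pathways with their
#' organisms.  This answers "which organisms carry the (map-level) pathway
#' this drug acts on, as evidenced by drug links".
#'
#' @param store A `wh_store` with resolved cross-references.
#' @param drugbank_id Query drug.
#' @return Data.frame `kegg_id`, `map_number`, `organism_tax_id`, sorted by
#'   kegg_id.
#' @export
drug_pathway_organisms <- function(store, drugbank_id) {
  q <- wh_lookup(store, "drug", drugbank_id)
  if (nrow(q) == 0) wh_usage_stop(sprintf("unknown drug %s", drugbank_id))
  maps <- wh_query(store,
    "SELECT DISTINCT p.MapNumber AS map FROM Drug_has_Protein dp
     JOIN Pathway_has_Protein pp ON pp.Protein_WID = dp.Protein_WID
     JOIN Pathway p ON p.WID = pp.Pathway_WID
     WHERE dp.Drug_WID = ?", params = list(q$wid[1]))$map
  if (length(maps) == 0)
    return(data.frame(kegg_id = character(0), map_number = character(0),
                      organism_tax_id = integer(0)))
  hits <- wh_query(store, sprintf(
    "SELECT DISTINCT p.KeggId AS kegg_id, p.MapNumber AS map_number,
            p.OrganismTaxId AS organism_tax_id
     FROM Pathway p
     JOIN Pathway_has_Protein pp ON pp.Pathway_WID = p.WID
     JOIN Drug_has_Protein dp ON dp.Protein_WID = pp.Protein_WID
     WHERE p.MapNumber IN (%s) ORDER BY p.KeggId",
    paste(rep("?", length(maps)), collapse = ",")), params = as.list(maps))
  hits$organism_tax_id <- as.integer(hits$organism_tax_id)
  hits
}
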