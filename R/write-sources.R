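# Serializing a fixture spec into valid files of every source dialect, and
# reading a loaded store back out as a spec (the round-trip counterpart).

wh_write_taxdump <- function(spec, dir) {
  taxa <- spec$taxonomy
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|", taxa$tax_id, taxa$parent_tax_id,
                   taxa$rank)
  writeLines(nodes, file.path(dir, "nodes.dmp"), useBytes = TRUE)
  name_lines <- character(0)
  for (i in seq_len(nrow(taxa))) {
    if (!is.na(taxa$scientific_name[i]))
      name_lines <- c(name_lines, sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                                          taxa$tax_id[i], taxa$scientific_name[i]))
    for (s in taxa$synonyms[[i]])
      name_lines <- c(name_lines, sprintf("%d\t|\t%s\t|\t\t|\tsynonym\t|",
                                          taxa$tax_id[i], s))
  }
  writeLines(name_lines, file.path(dir, "names.dmp"), useBytes = TRUE)
  dir
}

wh_write_gene_info <- function(spec, file) {
  g <- spec$gene
  syn <- vapply(g$synonyms, function(s)
    if (length(s) == 0) "-" else paste(s, collapse = "|"), character(1))
  lines <- c("#tax_id\tGeneID\tSymbol\tLocusTag\tSynonyms",
             sprintf("%d\t%d\t%s\t%s\t%s", g$tax_id, g$gene_id, g$symbol,
                     g$locus_tag, syn))
  writeLines(lines, file, useBytes = TRUE)
  file
}

wh_write_ptt <- function(rows, file) {
  hdr <- c(sprintf("%s synthetic replicon, complete sequence - 1..%d",
                   rows$replicon_accession[1], max(rows$end_bp, 0L) + 1000L),
           sprintf("%d proteins", nrow(rows)),
           "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct")
  body <- sprintf("%d..%d\t%s\t%d\t%s\t%s\t%s\t-\t-\t%s",
                  rows$start_bp, rows$end_bp, rows$strand,
                  pmax((rows$end_bp - rows$start_bp + 1L) %/% 3L - 1L, 1L),
                  rows$pid, rows$gene_symbol, rows$locus_tag, rows$product)
  writeLines(c(hdr, body), file, useBytes = TRUE)
  file
}

wh_write_uniprot <- function(spec, file) {
  doc <- xml2::xml_new_root("uniprot")
  p <- spec$protein
  for (i in seq_len(nrow(p))) {
    e <- xml2::xml_add_child(doc, "entry")
    for (a in p$accessions[[i]]) xml2::xml_add_child(e, "accession", a)
    pr <- xml2::xml_add_child(e, "protein")
    rn <- xml2::xml_add_child(pr, "recommendedName")
    xml2::xml_add_child(rn, "fullName", p$name[i])
    if (length(p$gene_locus_tags[[i]]) > 0) {
      ge <- xml2::xml_add_child(e, "gene")
      for (lt in p$gene_locus_tags[[i]])
        xml2::xml_add_child(ge, "name", lt, type = "ordered locus")
    }
    if (!is.na(p$tax_id[i])) {
      org <- xml2::xml_add_child(e, "organism")
      xml2::xml_add_child(org, "dbReference", type = "NCBI Taxonomy",
                          id = as.character(p$tax_id[i]))
    }
    xml2::xml_add_child(e, "sequence", p$sequence[i])
  }
  xml2::write_xml(doc, file)
  file
}

wh_write_uniref <- function(spec, file) {
  doc <- xml2::xml_new_root("UniRef100")
  u <- spec$uniref
  for (i in seq_len(nrow(u))) {
    e <- xml2::xml_add_child(doc, "entry", id = u$cluster_id[i])
    rm <- xml2::xml_add_child(e, "representativeMember")
    xml2::xml_add_child(rm, "dbReference", type = "UniProtKB ID",
                        id = u$representative_accession[i])
    for (m in u$member_accessions[[i]]) {
      me <- xml2::xml_add_child(e, "member")
      xml2::xml_add_child(me, "dbReference", type = "UniProtKB ID", id = m)
    }
  }
  xml2::write_xml(doc, file)
  file
}

wh_write_psimi <- function(rows, dataset, file) {
  doc <- xml2::xml_new_root("entrySet", level = "2", version = "5")
  e <- xml2::xml_add_child(doc, "entry")
  src <- xml2::xml_add_child(e, "source")
  nm <- xml2::xml_add_child(src, "names")
  xml2::xml_add_child(nm, "shortLabel", dataset)
  accs <- unique(c(rows$interactor_a, rows$interactor_b))
  il <- xml2::xml_add_child(e, "interactorList")
  ids <- stats::setNames(sprintf("i%d", seq_along(accs)), accs)
  for (a in accs) {
    it <- xml2::xml_add_child(il, "interactor", id = ids[[a]])
    xr <- xml2::xml_add_child(it, "xref")
    xml2::xml_add_child(xr, "primaryRef", db = "uniprotkb", id = a)
  }
  xl <- xml2::xml_add_child(e, "interactionList")
  for (i in seq_len(nrow(rows))) {
    ia <- xml2::xml_add_child(xl, "interaction")
    if (nzchar(rows$detection_method[i])) {
      n2 <- xml2::xml_add_child(ia, "names")
      xml2::xml_add_child(n2, "shortLabel", rows$detection_method[i])
    }
    if (nzchar(rows$pubmed_id[i])) {
      x2 <- xml2::xml_add_child(ia, "xref")
      xml2::xml_add_child(x2, "primaryRef", db = "pubmed", id = rows$pubmed_id[i])
    }
    pl <- xml2::xml_add_child(ia, "participantList")
    for (acc in c(rows$interactor_a[i], rows$interactor_b[i])) {
      pt <- xml2::xml_add_child(pl, "participant")
      xml2::xml_add_child(pt, "interactorRef", ids[[acc]])
    }
  }
  xml2::write_xml(doc, file)
  file
}

wh_write_drugbank <- function(spec, file) {
  doc <- xml2::xml_new_root("drugbank")
  d <- spec$drug
  for (i in seq_len(nrow(d))) {
    e <- xml2::xml_add_child(doc, "drug")
    xml2::xml_add_child(e, "drugbank-id", d$drugbank_id[i])
    xml2::xml_add_child(e, "name", d$name[i])
    xml2::xml_add_child(e, "description", d$description[i])
    tl <- xml2::xml_add_child(e, "targets")
    for (t in d$target_accessions[[i]]) {
      te <- xml2::xml_add_child(tl, "target")
      xml2::xml_add_child(te, "polypeptide", id = t, source = "Swiss-Prot")
    }
  }
  xml2::write_xml(doc, file)
  file
}

kegg_line <- function(kw, val) sprintf("%-12s%s", kw, val)
kegg_cont <- function(val) sprintf("%-12s%s", "", val)

wh_write_kegg_pathway <- function(spec, file) {
  p <- spec$pathway
  lines <- character(0)
  for (i in seq_len(nrow(p))) {
    lines <- c(lines, kegg_line("ENTRY", paste0(p$kegg_id[i], "            Pathway")))
    if (nzchar(p$name[i])) lines <- c(lines, kegg_line("NAME", p$name[i]))
    if (!is.na(p$organism_tax_id[i]))
      lines <- c(lines, kegg_line("ORGANISM",
                                  sprintf("taxon %d [TAX:%d]", p$organism_tax_id[i],
                                          p$organism_tax_id[i])))
    mem <- p$member_accessions[[i]]
    if (length(mem) > 0)
      lines <- c(lines, kegg_line("MEMBER", mem[1]),
                 if (length(mem) > 1) vapply(mem[-1], kegg_cont, character(1)))
    lines <- c(lines, "///")
  }
  writeLines(lines, file, useBytes = TRUE)
  file
}

wh_write_kegg_enzyme <- function(spec, file) {
  z <- spec$enzyme
  lines <- character(0)
  for (i in seq_len(nrow(z))) {
    lines <- c(lines, kegg_line("ENTRY", paste0("EC ", z$ec_number[i], "            Enzyme")))
    nm <- z$names[[i]]
    if (length(nm) > 0)
      lines <- c(lines, kegg_line("NAME", nm[1]),
                 if (length(nm) > 1) vapply(nm[-1], kegg_cont, character(1)))
    pa <- z$protein_accessions[[i]]
    if (length(pa) > 0)
      lines <- c(lines, kegg_line("PROTEIN", pa[1]),
                 if (length(pa) > 1) vapply(pa[-1], kegg_cont, character(1)))
    lines <- c(lines, "///")
  }
  writeLines(lines, file, useBytes = TRUE)
  file
}

wh_write_obo <- function(spec, file) {
  doc <- xml2::xml_new_root("obo")
  t <- spec$term
  for (i in seq_len(nrow(t))) {
    e <- xml2::xml_add_child(doc, "term")
    xml2::xml_add_child(e, "id", t$term_id[i])
    xml2::xml_add_child(e, "name", t$name[i])
    xml2::xml_add_child(e, "namespace", t$namespace[i])
    for (p in t$is_a_parents[[i]]) xml2::xml_add_child(e, "is_a", p)
  }
  xml2::write_xml(doc, file)
  file
}

#' Serialize a fixture spec into source files of every dialect
#'
#' Writes one file per supported source format (a taxdump nodes/names pair,
#' one PTT per replicon, one PSI-MI file per interaction dataset) plus a
#' JSON serialization of the spec itself.  Every written file parses back
#' losslessly with the corresponding parser.
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Manifest data.frame with columns `format` and `path`, usable
#'   with [load_sources()].
#' @export
write_sources <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create ", out_dir)
  manifest <- data.frame(format = character(0), path = character(0))
  add <- function(format, path)
    manifest <<- rbind(manifest, data.frame(format = format, path = path))
  wh_write_taxdump(spec, out_dir)
  add("taxdump", out_dir)
  add("gene_info", wh_write_gene_info(spec, file.path(out_dir, "gene_info.tsv")))
  for (r in unique(spec$ptt$replicon_accession)) {
    rows <- spec$ptt[spec$ptt$replicon_accession == r, , drop = FALSE]
    add("ptt", wh_write_ptt(rows, file.path(out_dir, paste0(r, ".ptt"))))
  }
  add("uniprot", wh_write_uniprot(spec, file.path(out_dir, "uniprot.xml")))
  add("uniref", wh_write_uniref(spec, file.path(out_dir, "uniref.xml")))
  for (ds in unique(spec$interaction$source_dataset)) {
    rows <- spec$interaction[spec$interaction$source_dataset == ds, , drop = FALSE]
    safe <- gsub("[^A-Za-z0-9]", "_", ds)
    add("psimi", wh_write_psimi(rows, ds,
                                file.path(out_dir, paste0("psimi_", safe, ".xml"))))
  }
  add("drugbank", wh_write_drugbank(spec, file.path(out_dir, "drugbank.xml")))
  add("kegg_pathway", wh_write_kegg_pathway(spec, file.path(out_dir, "kegg_pathway.keg")))
  add("kegg_enzyme", wh_write_kegg_enzyme(spec, file.path(out_dir, "kegg_enzyme.keg")))
  add("obo", wh_write_obo(spec, file.path(out_dir, "ontology.obo.xml")))
  write_spec_json(spec, file.path(out_dir, "fixture_spec.json"))
  manifest
}

#' Load a manifest of source files into a store
#'
#' Runs [wh_load()] for every manifest row and stops on the first failure;
#' cross-references are resolved afterwards.
#'
#' @param store A `wh_store`.
#' @param manifest Manifest from [write_sources()], or a directory written
#'   by it.
#' @return Named integer vector of link counts from [resolve_crossrefs()],
#'   invisibly.
#' @export
load_sources <- function(store, manifest) {
  if (is.character(manifest)) {
    dir <- manifest
    files <- list.files(dir, full.names = TRUE)
    manifest <- data.frame(format = character(0), path = character(0))
    grab <- function(format, path)
      if (length(path)) manifest <<- rbind(manifest,
                                           data.frame(format = format, path = path))
    if (file.exists(file.path(dir, "nodes.dmp"))) grab("taxdump", dir)
    grab("gene_info", files[basename(files) == "gene_info.tsv"])
    grab("ptt", files[grepl("\\.ptt$", files)])
    grab("uniprot", files[basename(files) == "uniprot.xml"])
    grab("uniref", files[basename(files) == "uniref.xml"])
    grab("psimi", files[grepl("^psimi_.*\\.xml$", basename(files))])
    grab("drugbank", files[basename(files) == "drugbank.xml"])
    grab("kegg_pathway", files[basename(files) == "kegg_pathway.keg"])
    grab("kegg_enzyme", files[basename(files) == "kegg_enzyme.keg"])
    grab("obo", files[basename(files) == "ontology.obo.xml"])
  }
  for (i in seq_len(nrow(manifest))) {
    rep <- wh_load(store, manifest$path[i], manifest$format[i])
    if (!is.null(rep$failure))
      stop("load failed for ", manifest$path[i], ": ", rep$failure$message,
           call. = FALSE)
  }
  invisible(resolve_crossrefs(store))
}

#' Generate, serialize and load a world in one step
#'
#' @param store A `wh_store`.
#' @param spec A `fixture_spec` (e.g. [paper_facts()]).
#' @param dir Scratch directory for the serialized sources.
#' @return The store, invisibly.
#' @export
load_world <- function(store, spec, dir = tempfile("world")) {
  manifest <- write_sources(spec, dir)
  load_sources(store, manifest)
  invisible(store)
}

#' Export a loaded store back into a fixture spec
#'
#' Reconstructs the record frames of every entity kind from the relational
#' tables (in WID order); together with [write_sources()] this closes the
#' generate - write - parse - load - export round trip.
#'
#' @param store A `wh_store`.
#' @return A `fixture_spec` (seed `NA`).
#' @export
store_to_spec <- function(store) {
  tables <- lapply(wh_kinds(), function(k) {
    d <- wh_get(store, k)
    d$wid <- NULL
    d
  })
  names(tables) <- wh_kinds()
  fixture_spec(tables)
}
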