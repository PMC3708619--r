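# Declarative synthetic worlds.
#
# A fixture spec is a named list of entity record frames (one per kind in
# wh_kinds()) plus a seed; it is referentially consistent, serializable as
# JSON, and can be written out as valid files of every supported source
# dialect by write_sources().  It doubles as the ground truth that oracle
# tests recompute joins from.

fixture_spec <- function(tables, seed = NA_integer_) {
  spec <- lapply(wh_kinds(), function(k) {
    if (!is.null(tables[[k]])) wh_records(k, tables[[k]]) else wh_empty_records(k)
  })
  names(spec) <- wh_kinds()
  spec$seed <- as.integer(seed)
  class(spec) <- "fixture_spec"
  spec
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture spec>", if (!is.na(x$seed)) paste0(" seed ", x$seed), "\n", sep = "")
  for (k in wh_kinds()) cat(sprintf("  %-12s %d\n", k, nrow(x[[k]])))
  invisible(x)
}

#' Validate the referential consistency of a fixture spec
#'
#' Checks every per-record invariant plus cross-table references: taxonomy
#' parents form a single rooted tree, genes and proteins point at defined
#' taxa, PTT locus tags and protein locus tags at defined genes, and every
#' accession referenced by clusters, interactions, drugs, pathways or
#' enzymes is a defined protein accession.  A PTT `pid` of `"-"` means "no
#' protein" and is exempt.
#'
#' @param spec A `fixture_spec`.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (k in wh_kinds()) wh_validate_rows(k, spec[[k]])
  fail <- function(...) wh_constraint_stop(sprintf(...))
  taxa <- spec$taxonomy
  if (nrow(taxa) > 0) {
    roots <- taxa$tax_id[taxa$parent_tax_id == taxa$tax_id]
    if (length(roots) != 1) fail("taxonomy must have exactly one root")
    if (!all(taxa$parent_tax_id %in% taxa$tax_id)) fail("undefined parent_tax_id")
  }
  tax_ids <- taxa$tax_id
  loci <- toupper(spec$gene$locus_tag)
  accs <- toupper(unlist(spec$protein$accessions))
  chk_tax <- function(x, what) {
    bad <- setdiff(x[!is.na(x)], tax_ids)
    if (length(bad)) fail("%s references undefined tax_id %s", what, bad[1])
  }
  chk_acc <- function(x, what) {
    bad <- setdiff(toupper(x), accs)
    if (length(bad)) fail("%s references undefined accession %s", what, bad[1])
  }
  chk_tax(spec$gene$tax_id, "gene")
  chk_tax(spec$protein$tax_id, "protein")
  chk_tax(spec$pathway$organism_tax_id, "pathway")
  bad <- setdiff(toupper(spec$ptt$locus_tag), loci)
  if (length(bad)) fail("ptt references undefined locus_tag %s", bad[1])
  pid <- spec$ptt$pid
  chk_acc(pid[pid != "-"], "ptt pid")
  bad <- setdiff(toupper(unlist(spec$protein$gene_locus_tags)), loci)
  if (length(bad)) fail("protein references undefined locus_tag %s", bad[1])
  chk_acc(unlist(spec$uniref$member_accessions), "uniref")
  chk_acc(c(spec$interaction$interactor_a, spec$interaction$interactor_b), "interaction")
  chk_acc(unlist(spec$drug$target_accessions), "drug")
  chk_acc(unlist(spec$pathway$member_accessions), "pathway")
  chk_acc(unlist(spec$enzyme$protein_accessions), "enzyme")
  bad <- setdiff(toupper(unlist(spec$term$is_a_parents)), toupper(spec$term$term_id))
  if (length(bad)) fail("term references undefined parent %s", bad[1])
  invisible(TRUE)
}

#' The built-in world encoding the printed worked-example relations
#'
#' A small bacterial world built from relations printed in public database
#' records: the Streptococcus pneumoniae R6 gene spr0328 (protein Q8DR60)
#' with its chromosomal neighbor spr0329 (GeneID 934791, protein Q8DR59, a
#' penicillin-binding protein targeted by nine beta-lactam antibiotics);
#' Hetacillin (DB00739) acting on PBPA_STRR6 and PBP2_STRR6, both members
#' of the peptidoglycan-biosynthesis pathway spr00550 of R6 (tax 171101); a
#' TIGR4 ortholog neighborhood whose gene 930269 encodes an antibiotic
#' target, and TIGR4 target genes 930802/930805 lying within 5000 bp;
#' Ceftazidime (DB00438) and Cyclacillin (DB01000) acting on map-00550
#' pathways of E. coli MG1655 (511145) and C. perfringens 13 (195102); plus
#' filler genes, drugs and a human control protein so negative controls
#' exist.  Invented details -- all coordinates, sequences, filler names,
#' the TIGR4 strain taxid (1313901) and the non-printed DrugBank ids -- are
#' arbitrary and only preserve the printed order/distance constraints.
#'
#' @return A validated `fixture_spec`.
#' @export
paper_facts <- function() {
  taxonomy <- data.frame(
    tax_id = c(1L, 2L, 9606L, 1301L, 1313L, 171101L, 1313901L, 32008L,
               511145L, 195102L),
    parent_tax_id = c(1L, 1L, 1L, 2L, 1301L, 1313L, 1313L, 2L, 2L, 2L),
    rank = c("no rank", "superkingdom", "species", "genus", "species",
             "strain", "strain", "genus", "strain", "strain"),
    scientific_name = c("root", "Bacteria", "Homo sapiens", "Streptococcus",
                        "Streptococcus pneumoniae",
                        "Streptococcus pneumoniae R6",
                        "Streptococcus pneumoniae TIGR4 (synthetic taxid)",
                        "Burkholderia",
                        "Escherichia coli str. K-12 substr. MG1655",
                        "Clostridium perfringens str. 13"))
  taxonomy$synonyms <- empty_chr_list(nrow(taxonomy))
  taxonomy$synonyms[[2]] <- "eubacteria"
  taxonomy$synonyms[[3]] <- c("human", "man")
  taxonomy$synonyms[[5]] <- "pneumococcus"

  # --- R6 chromosome: spr0310..spr0340 plus the distant pbp1A locus ------
  r6_loci <- sprintf("spr%04d", 310:340)
  r6_ids <- 910310:910340
  r6_ids[r6_loci == "spr0328"] <- 934790L
  r6_ids[r6_loci == "spr0329"] <- 934791L
  # --- TIGR4 chromosome: ortholog neighborhood + distant target block ---
  t4_loci <- sprintf("spt%04d", 318:338)
  t4_ids <- 920318:920338
  t4_ids[t4_loci == "spt0328"] <- 930268L
  t4_ids[t4_loci == "spt0329"] <- 930269L
  t4r_loci <- sprintf("spt%04d", 801:806)
  t4r_ids <- 930801:930806

  gene <- data.frame(
    gene_id = c(r6_ids, 911800L, t4_ids, t4r_ids,
                945001L, 945003L, 945004L, 945005L, 988001L, 988002L),
    locus_tag = c(r6_loci, "spr1800", t4_loci, t4r_loci,
                  "b0635", "b0181", "b0090", "b4150", "CPE0780", "CPE0999"),
    symbol = c(r6_loci, "pbp1A", t4_loci, t4r_loci,
               "mrdA", "lpxA", "murG", "ampC", "pbpB", "isoA"),
    tax_id = c(rep(171101L, length(r6_loci) + 1L),
               rep(1313901L, length(t4_loci) + length(t4r_loci)),
               rep(511145L, 4L), rep(195102L, 2L)))
  gene$symbol[gene$locus_tag == "spr0328"] <- "eng"
  gene$symbol[gene$locus_tag == "spr0329"] <- "pbp2B"
  gene$synonyms <- empty_chr_list(nrow(gene))
  gene$synonyms[[which(gene$locus_tag == "spr0329")]] <- "penA"

  pid_of <- c(spr0328 = "Q8DR60", spr0329 = "Q8DR59", spr0315 = "FILR61",
              spr0320 = "FILR62", spr1800 = "PBPA_STRR6",
              spt0328 = "Q97TIG4", spt0329 = "PBPX_STRPT",
              spt0802 = "PBPC_STRPT", spt0805 = "PBPD_STRPT")
  mk_ptt <- function(replicon, loci, starts, len) {
    data.frame(replicon_accession = replicon, start_bp = as.integer(starts),
               end_bp = as.integer(starts + len), strand = rep(c("+", "-"),
               length.out = length(loci)),
               pid = ifelse(is.na(pid_of[loci]), "-", pid_of[loci]),
               gene_symbol = gene$symbol[match(loci, gene$locus_tag)],
               locus_tag = loci,
               product = ifelse(is.na(pid_of[loci]), "hypothetical protein",
                                "annotated protein"))
  }
  ptt <- rbind(
    mk_ptt("NC_003098", r6_loci, 10000 + (seq_along(r6_loci) - 1) * 1200, 899L),
    mk_ptt("NC_003098", "spr1800", 1800000, 899L),
    mk_ptt("NC_003028", t4_loci, 20000 + (seq_along(t4_loci) - 1) * 1100, 799L),
    mk_ptt("NC_003028", t4r_loci,
           c(300000, 301200, 302300, 303100, 305000, 306500),
           c(900L, 800L, 600L, 600L, 600L, 500L)))

  protein <- data.frame(
    primary_accession = c("Q8DR59", "PBPA_STRR6", "Q8DR60", "Q97TIG4",
                          "PBPX_STRPT", "PBPC_STRPT", "PBPD_STRPT",
                          "MRDA_ECOLI", "MURG_ECOLI", "LPXA_ECOLI",
                          "AMPC_ECOLI", "PBPB_CLOPE", "ISOA_CLOPE",
                          "P99998", "FILR61", "FILR62"),
    name = c("Penicillin-binding protein 2B",
             "Penicillin-binding protein 1A",
             "Endo-alpha-N-acetylgalactosaminidase",
             "Endo-alpha-N-acetylgalactosaminidase ortholog (synthetic)",
             "Penicillin-binding protein (synthetic TIGR4)",
             "Penicillin-binding protein C (synthetic TIGR4)",
             "Penicillin-binding protein D (synthetic TIGR4)",
             "Peptidoglycan D,D-transpeptidase MrdA",
             "UDP-GlcNAc transferase MurG",
             "Acyl-ACP UDP-GlcNAc acyltransferase LpxA",
             "Beta-lactamase AmpC",
             "Penicillin-binding protein (C. perfringens)",
             "Isolated synthetic protein",
             "Synthetic human control protein",
             "Filler protein 1 (synthetic)", "Filler protein 2 (synthetic)"),
    tax_id = c(171101L, 171101L, 171101L, 1313901L, 1313901L, 1313901L,
               1313901L, 511145L, 511145L, 511145L, 511145L, 195102L,
               195102L, 9606L, 171101L, 171101L))
  protein$accessions <- as.list(protein$primary_accession)
  protein$accessions[[1]] <- c("Q8DR59", "PBP2_STRR6")
  protein$gene_locus_tags <- list(
    "spr0329", "spr1800", "spr0328", "spt0328", "spt0329", "spt0802",
    "spt0805", "b0635", "b0090", "b0181", "b4150", "CPE0780", "CPE0999",
    character(0), "spr0315", "spr0320")
  protein$sequence <- with_seed(104729L, vapply(
    seq_len(nrow(protein)), function(i) random_aa_seq(30L), character(1)))
  protein$sequence[1] <- "MKLSERLDQVAKDAGIKWTALAVGAFSVLLVAQALNLL"

  uniref <- data.frame(
    cluster_id = c("UniRef100_Q8DR60", "UniRef100_Q8DR59"),
    representative_accession = c("Q8DR60", "Q8DR59"))
  uniref$member_accessions <- list(c("Q8DR60", "Q97TIG4"),
                                   c("Q8DR59", "PBPX_STRPT"))

  interaction <- data.frame(
    source_dataset = c("IntAct", "IntAct", "MINT", "IntAct"),
    interactor_a = c("Q8DR59", "Q8DR60", "Q8DR59", "PBPA_STRR6"),
    interactor_b = c("PBPA_STRR6", "Q8DR59", "PBPA_STRR6", "PBPA_STRR6"),
    detection_method = c("two hybrid", "pull down", "two hybrid", "two hybrid"),
    pubmed_id = c("12345678", "12345679", "22345678", "12345680"))

  drug <- data.frame(
    drugbank_id = c("DB00713", "DB00739", "DB00607", "DB00415", "DB00456",
                    "DB01061", "DB00493", "DB01331", "DB00567", "DB00438",
                    "DB01000", "DB09001", "DB09002", "DB09003", "DB09004"),
    name = c("Oxacillin", "Hetacillin", "Nafcillin", "Ampicillin",
             "Cefalotin", "Azidocillin", "Cefotaxime", "Cefoxitin",
             "Cephalexin", "Ceftazidime", "Cyclacillin", "Moenomycin A",
             "Lipoxamycin (synthetic)", "Isolatin (synthetic)",
             "Placebomycin (synthetic)"),
    description = "beta-lactam class antibacterial agent")
  drug$description[12:15] <- "synthetic filler drug"
  drug$target_accessions <- list(
    c("Q8DR59", "PBPX_STRPT"),        # Oxacillin
    c("PBPA_STRR6", "PBP2_STRR6"),    # Hetacillin: only its two printed targets
    "Q8DR59",                          # Nafcillin
    c("Q8DR59", "MRDA_ECOLI"),        # Ampicillin (bridges to E. coli)
    "Q8DR59",                          # Cefalotin
    "Q8DR59",                          # Azidocillin
    c("Q8DR59", "PBPC_STRPT"),        # Cefotaxime
    c("Q8DR59", "PBPD_STRPT"),        # Cefoxitin
    "Q8DR59",                          # Cephalexin
    "MRDA_ECOLI",                      # Ceftazidime
    "PBPB_CLOPE",                      # Cyclacillin
    "MURG_ECOLI",                      # Moenomycin A
    "LPXA_ECOLI",                      # Lipoxamycin
    "ISOA_CLOPE",                      # Isolatin
    character(0))                      # Placebomycin

  pathway <- data.frame(
    kegg_id = c("spr00550", "eco00550", "cpe00550", "eco00540", "cpe00999"),
    name = c("Peptidoglycan biosynthesis", "Peptidoglycan biosynthesis",
             "Peptidoglycan biosynthesis", "Lipopolysaccharide biosynthesis",
             "Isolated synthetic pathway"),
    organism_tax_id = c(171101L, 511145L, 195102L, 511145L, 195102L),
    map_number = c("00550", "00550", "00550", "00540", "00999"))
  pathway$member_accessions <- list(
    c("PBPA_STRR6", "PBP2_STRR6"),
    c("MRDA_ECOLI", "MURG_ECOLI"),
    "PBPB_CLOPE",
    c("LPXA_ECOLI", "MURG_ECOLI"),
    "ISOA_CLOPE")

  enzyme <- data.frame(ec_number = c("3.5.2.6", "2.4.1.227"))
  enzyme$names <- list(c("beta-lactamase", "penicillinase"),
                       "undecaprenyl-diphospho-muramoylpentapeptide beta-N-acetylglucosaminyltransferase")
  enzyme$protein_accessions <- list("AMPC_ECOLI", "MURG_ECOLI")

  term <- data.frame(
    term_id = c("GO:0008150", "GO:0009058", "GO:0009252"),
    name = c("biological_process", "biosynthetic process",
             "peptidoglycan biosynthetic process"),
    namespace = "biological_process")
  term$is_a_parents <- list(character(0), "GO:0008150", "GO:0009058")

  spec <- fixture_spec(list(
    taxonomy = taxonomy, gene = gene, ptt = ptt, protein = protein,
    uniref = uniref, interaction = interaction, drug = drug,
    pathway = pathway, enzyme = enzyme, term = term))
  validate_spec(spec)
  spec
}

#' Generate a seeded random world
#'
#' Produces a uniformly random but referentially consistent fixture spec of
#' the requested sizes; the same seed always yields the identical spec.
#' Genes are laid out on replicons with increasing non-overlapping
#' coordinates; a prefix of the genes encodes proteins (so a world never
#' holds more proteins than genes); clusters partition a subset of the
#' proteins; drugs, pathways and enzymes reference random protein
#' accessions.
#'
#' @param seed Integer RNG seed.
#' @param sizes Named list overriding any of: taxa, replicons, genes,
#'   proteins, clusters, interactions, datasets, drugs, pathways, enzymes,
#'   terms.
#' @return A validated `fixture_spec`.
#' @export
random_world <- function(seed, sizes = list()) {
  sz <- utils::modifyList(list(
    taxa = 8L, replicons = 2L, genes = 30L, proteins = 24L, clusters = 4L,
    interactions = 20L, datasets = 2L, drugs = 8L, pathways = 6L,
    enzymes = 3L, terms = 6L), sizes)
  sz <- lapply(sz, as.integer)
  with_seed(seed, {
    # taxonomy: random rooted tree
    taxonomy <- wh_empty_records("taxonomy")
    if (sz$taxa > 0) {
      ids <- sort(sample(2:99999, sz$taxa))
      parent <- ids
      if (sz$taxa > 1)
        for (i in 2:sz$taxa) parent[i] <- ids[sample.int(i - 1L, 1L)]
      taxonomy <- data.frame(
        tax_id = ids, parent_tax_id = parent,
        rank = sample(c("no rank", "genus", "species", "strain"), sz$taxa,
                      replace = TRUE),
        scientific_name = sprintf("Taxon %d", ids))
      taxonomy$synonyms <- lapply(ids, function(id) {
        k <- sample(0:2, 1)
        if (k == 0) character(0) else sprintf("syn%d_%d", id, seq_len(k))
      })
    }
    # replicons on random taxa
    n_rep <- if (sz$genes > 0) max(1L, sz$replicons) else sz$replicons
    rep_acc <- sprintf("NC_9%05d", seq_len(n_rep))
    rep_tax <- if (sz$taxa > 0) sample(taxonomy$tax_id, n_rep, replace = TRUE)
               else rep(NA_integer_, n_rep)
    # genes laid out along replicons
    gene <- wh_empty_records("gene")
    ptt <- wh_empty_records("ptt")
    if (sz$genes > 0) {
      g_rep <- sort(sample.int(n_rep, sz$genes, replace = TRUE))
      locus <- sprintf("loc%04d", seq_len(sz$genes))
      gene <- data.frame(
        gene_id = sort(sample(100000:999999, sz$genes)),
        locus_tag = locus,
        symbol = sprintf("g%d", seq_len(sz$genes)),
        tax_id = rep_tax[g_rep])
      gene$synonyms <- lapply(seq_len(sz$genes), function(i) {
        k <- sample(0:1, 1)
        if (k == 0) character(0) else sprintf("gsyn%d", i)
      })
      starts <- integer(sz$genes)
      for (r in seq_len(n_rep)) {
        idx <- which(g_rep == r)
        pos <- 1L
        for (i in idx) {
          pos <- pos + sample(50:2000, 1)
          starts[i] <- pos
          pos <- pos + sample(300:1500, 1)
        }
      }
      lens <- sample(300:1500, sz$genes, replace = TRUE)
      ptt <- data.frame(
        replicon_accession = rep_acc[g_rep],
        start_bp = starts, end_bp = starts + lens,
        strand = sample(c("+", "-"), sz$genes, replace = TRUE),
        pid = "-", gene_symbol = gene$symbol, locus_tag = locus,
        product = sprintf("product %d", seq_len(sz$genes)))
    }
    # proteins on a prefix of the genes
    n_prot <- min(sz$proteins, sz$genes)
    protein <- wh_empty_records("protein")
    if (n_prot > 0) {
      acc <- sprintf("AC%05d", seq_len(n_prot))
      protein <- data.frame(
        primary_accession = acc,
        name = sprintf("Protein %d", seq_len(n_prot)),
        sequence = vapply(seq_len(n_prot), function(i) random_aa_seq(30L),
                          character(1)),
        tax_id = gene$tax_id[seq_len(n_prot)])
      protein$accessions <- lapply(seq_len(n_prot), function(i) {
        if (stats::runif(1) < 0.3) c(acc[i], sprintf("SE%05d", i)) else acc[i]
      })
      protein$gene_locus_tags <- as.list(gene$locus_tag[seq_len(n_prot)])
      ptt$pid[seq_len(n_prot)] <- acc
    }
    all_acc <- unlist(protein$accessions) %||% character(0)
    pick_acc <- function(kmax) {
      if (length(all_acc) == 0) return(character(0))
      k <- sample(0:min(kmax, length(all_acc)), 1)
      if (k == 0) character(0) else sample(all_acc, k)
    }
    # clusters partition a shuffled subset of proteins
    uniref <- wh_empty_records("uniref")
    n_cl <- min(sz$clusters, n_prot)
    if (n_cl > 0) {
      shuffled <- sample(protein$primary_accession)
      grp <- sort(rep_len(seq_len(n_cl), length(shuffled)))
      members <- split(shuffled, grp)
      uniref <- data.frame(
        cluster_id = sprintf("CL%03d", seq_len(n_cl)),
        representative_accession = vapply(members, `[`, "", 1))
      uniref$member_accessions <- unname(members)
    }
    # interactions: unique (dataset, pair, method, pubmed) tuples
    interaction <- wh_empty_records("interaction")
    if (sz$interactions > 0 && length(all_acc) >= 1) {
      ds <- sprintf("DS%d", seq_len(max(1L, sz$datasets)))
      seen <- character(0)
      rows <- list()
      attempts <- 0L
      while (length(rows) < sz$interactions && attempts < sz$interactions * 20L) {
        attempts <- attempts + 1L
        a <- sample(all_acc, 1)
        b <- if (stats::runif(1) < 0.1) a else sample(all_acc, 1)
        r <- list(source_dataset = sample(ds, 1), interactor_a = a,
                  interactor_b = b,
                  detection_method = sprintf("method %d", sample.int(4, 1)),
                  pubmed_id = sprintf("%08d", sample.int(99999999L, 1)))
        key <- paste(r$source_dataset, paste(sort(toupper(c(a, b))), collapse = "|"),
                     r$detection_method, r$pubmed_id)
        if (key %in% seen) next
        seen <- c(seen, key)
        rows[[length(rows) + 1L]] <- r
      }
      interaction <- do.call(rbind, lapply(rows, as.data.frame))
    }
    # drugs
    drug <- wh_empty_records("drug")
    if (sz$drugs > 0) {
      drug <- data.frame(
        drugbank_id = sprintf("DB9%04d", seq_len(sz$drugs)),
        name = sprintf("Drug %d", seq_len(sz$drugs)),
        description = sprintf("synthetic drug %d", seq_len(sz$drugs)))
      drug$target_accessions <- lapply(seq_len(sz$drugs), function(i) pick_acc(3))
    }
    # pathways (unique org code + 5-digit map number)
    pathway <- wh_empty_records("pathway")
    if (sz$pathways > 0) {
      code <- vapply(seq_len(sz$pathways), function(i)
        paste0("z", letters[(i - 1L) %% 26L + 1L], letters[(i - 1L) %/% 26L + 1L]),
        character(1))
      maps <- sprintf("%05d", sample(1:999, sz$pathways, replace = TRUE))
      pathway <- data.frame(
        kegg_id = paste0(code, maps),
        name = sprintf("Pathway %d", seq_len(sz$pathways)),
        organism_tax_id = if (sz$taxa > 0)
          sample(taxonomy$tax_id, sz$pathways, replace = TRUE)
          else rep(NA_integer_, sz$pathways),
        map_number = maps)
      pathway$member_accessions <- lapply(seq_len(sz$pathways),
                                          function(i) pick_acc(4))
    }
    enzyme <- wh_empty_records("enzyme")
    if (sz$enzymes > 0) {
      enzyme <- data.frame(ec_number = sprintf("1.2.3.%d", seq_len(sz$enzymes)))
      enzyme$names <- lapply(seq_len(sz$enzymes), function(i)
        sprintf("enzyme %d name %d", i, seq_len(sample(1:2, 1))))
      enzyme$protein_accessions <- lapply(seq_len(sz$enzymes),
                                          function(i) pick_acc(2))
    }
    term <- wh_empty_records("term")
    if (sz$terms > 0) {
      tid <- sprintf("GO:%07d", seq_len(sz$terms))
      term <- data.frame(term_id = tid,
                         name = sprintf("term %d", seq_len(sz$terms)),
                         namespace = "biological_process")
      term$is_a_parents <- lapply(seq_len(sz$terms), function(i) {
        if (i == 1) return(character(0))
        k <- sample(0:min(2, i - 1L), 1)
        if (k == 0) character(0) else sample(tid[seq_len(i - 1L)], k)
      })
    }
    spec <- fixture_spec(list(
      taxonomy = taxonomy, gene = gene, ptt = ptt, protein = protein,
      uniref = uniref, interaction = interaction, drug = drug,
      pathway = pathway, enzyme = enzyme, term = term), seed = seed)
    validate_spec(spec)
    spec
  })
}

# Canonical ordering for spec comparison (round trips, oracles).
normalize_spec <- function(spec) {
  ord <- list(
    taxonomy = function(d) order(d$tax_id),
    gene = function(d) order(d$gene_id),
    ptt = function(d) order(d$replicon_accession, d$start_bp, d$locus_tag),
    protein = function(d) order(d$primary_accession),
    interaction = function(d) order(d$source_dataset, d$interactor_a,
                                    d$interactor_b, d$detection_method,
                                    d$pubmed_id),
    uniref = function(d) order(d$cluster_id),
    drug = function(d) order(d$drugbank_id),
    pathway = function(d) order(d$kegg_id),
    enzyme = function(d) order(d$ec_number),
    term = function(d) order(d$term_id))
  out <- lapply(wh_kinds(), function(k) {
    d <- spec[[k]]
    d <- d[ord[[k]](d), , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "wh_kind") <- NULL
    for (col in names(d)) if (is.list(d[[col]]))
      d[[col]] <- lapply(d[[col]], unname)
    d
  })
  names(out) <- wh_kinds()
  out
}

#' Serialize a fixture spec to a JSON file
#' @param spec A `fixture_spec`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_spec_json <- function(spec, file) {
  payload <- lapply(wh_kinds(), function(k) spec[[k]])
  names(payload) <- wh_kinds()
  payload$seed <- spec$seed
  jsonlite::write_json(payload, file, dataframe = "columns", null = "null",
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
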