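# Strict parsing of each source dialect, and loader atomicity.

test_that("taxonomy dump parsing: minimal root, synonym classes, strictness", {
  nodes <- "1\t|\t1\t|\tno rank\t|"
  names_ <- c("1\t|\troot\t|\t\t|\tscientific name\t|",
              "1\t|\tall\t|\t\t|\tsynonym\t|")
  taxa <- parse_taxonomy_dump(nodes, paste(names_, collapse = "\n"))
  expect_equal(nrow(taxa), 1)
  expect_equal(taxa$scientific_name, "root")
  expect_equal(taxa$synonyms[[1]], "all")

  expect_error(parse_taxonomy_dump(nodes, "999\t|\tghost\t|\t\t|\tsynonym\t|"),
               class = "wh_parse_error")
  expect_error(parse_taxonomy_dump("x\t|\t1\t|\tno rank\t|", names_[1]),
               class = "wh_parse_error")
  expect_error(parse_taxonomy_dump("1\t|\t1\t|", names_[1]),
               class = "wh_parse_error")
})

test_that("gene_info parsing extracts ids, locus tags and synonyms", {
  txt <- paste(c("#tax_id\tGeneID\tSymbol\tLocusTag\tSynonyms",
                 "171101\t934791\tpbp2B\tspr0329\tpenA|pbpB",
                 "171101\t934790\teng\tspr0328\t-"), collapse = "\n")
  g <- parse_gene_info(txt)
  expect_equal(g$gene_id, c(934791L, 934790L))
  expect_equal(g$locus_tag, c("spr0329", "spr0328"))
  expect_equal(g$synonyms[[1]], c("penA", "pbpB"))
  expect_equal(g$synonyms[[2]], character(0))

  expect_equal(nrow(parse_gene_info("#tax_id\tGeneID\tSymbol\tLocusTag\tSynonyms")), 0)
  expect_error(parse_gene_info("171101\tabc\tx\ty\t-"), class = "wh_parse_error")
})

test_that("PTT parsing splits locations and enforces coordinate order", {
  hdr <- c("NC_003098 chromosome, complete sequence - 1..2038615",
           "2 proteins",
           "Location\tStrand\tLength\tPID\tGene\tSynonym\tCode\tCOG\tProduct")
  row1 <- "190..255\t+\t21\t16758994\tdnaA\tspr0001\t-\t-\tinitiator protein"
  p <- parse_ptt(paste(c(hdr, row1), collapse = "\n"))
  expect_equal(p$start_bp, 190L)
  expect_equal(p$end_bp, 255L)
  expect_equal(p$replicon_accession, "NC_003098")
  expect_equal(p$locus_tag, "spr0001")

  expect_equal(nrow(parse_ptt(paste(hdr, collapse = "\n"))), 0)
  bad <- "255..190\t+\t21\tX\tg\tl\t-\t-\tp"
  expect_error(parse_ptt(paste(c(hdr, bad), collapse = "\n")),
               class = "wh_parse_error")
})

test_that("UniProt XML parsing: primary accession ordering, sequence normalization", {
  xml <- '<uniprot><entry>
    <accession>Q8DR59</accession><accession>PBP2_STRR6</accession>
    <protein><recommendedName><fullName>PBP 2B</fullName></recommendedName></protein>
    <gene><name type="ordered locus">spr0329</name></gene>
    <organism><dbReference type="NCBI Taxonomy" id="171101"/></organism>
    <sequence>mklv aast</sequence>
  </entry></uniprot>'
  p <- parse_uniprot_xml(xml)
  expect_equal(p$primary_accession, "Q8DR59")
  expect_equal(p$accessions[[1]], c("Q8DR59", "PBP2_STRR6"))
  expect_equal(p$sequence, "MKLVAAST")
  expect_equal(p$tax_id, 171101L)
  expect_equal(p$gene_locus_tags[[1]], "spr0329")

  expect_error(parse_uniprot_xml("<uniprot><entry><sequence>MK</sequence></entry></uniprot>"),
               class = "wh_parse_error")
  expect_error(parse_uniprot_xml("<uniprot><entry><accession>A1</accession></entry></uniprot>"),
               class = "wh_parse_error")
})

test_that("UniRef XML parsing includes the representative among members", {
  xml <- '<UniRef100><entry id="UniRef100_Q8DR59">
    <representativeMember><dbReference type="UniProtKB ID" id="Q8DR59"/></representativeMember>
    <member><dbReference type="UniProtKB ID" id="PBP_TIGR4_X"/></member>
  </entry></UniRef100>'
  u <- parse_uniref_xml(xml)
  expect_equal(u$member_accessions[[1]], c("Q8DR59", "PBP_TIGR4_X"))
  expect_equal(nrow(parse_uniref_xml("<UniRef100/>")), 0)
  expect_error(parse_uniref_xml('<UniRef100><entry id="c1"><member><dbReference id="A"/></member></entry></UniRef100>'),
               class = "wh_parse_error")
  # one accession claimed by two clusters is a constraint violation
  two <- '<UniRef100>
    <entry id="c1"><representativeMember><dbReference id="A"/></representativeMember></entry>
    <entry id="c2"><representativeMember><dbReference id="A"/></representativeMember></entry>
  </UniRef100>'
  expect_error(parse_uniref_xml(two), class = "wh_constraint_error")
})

psimi_doc <- function(participants, roles = NULL, datasets = "IntAct") {
  refs <- paste0(sprintf('<interactor id="i%d"><xref><primaryRef db="uniprotkb" id="%s"/></xref></interactor>',
                         seq_along(participants), participants), collapse = "")
  parts <- paste0(vapply(seq_along(participants), function(i) {
    role <- if (!is.null(roles) && nzchar(roles[i]))
      sprintf("<experimentalRoleList><experimentalRole><names><shortLabel>%s</shortLabel></names></experimentalRole></experimentalRoleList>",
              roles[i]) else ""
    sprintf("<participant><interactorRef>i%d</interactorRef>%s</participant>", i, role)
  }, character(1)), collapse = "")
  sprintf('<entrySet><entry>
    <source><names><shortLabel>%s</shortLabel></names></source>
    <interactorList>%s</interactorList>
    <interactionList><interaction><participantList>%s</participantList></interaction></interactionList>
  </entry></entrySet>', datasets[1], refs, parts)
}

test_that("PSI-MI parsing: binary, n-ary expansion, dataset identity", {
  bin <- parse_psimi25(psimi_doc(c("A", "B")))
  expect_equal(nrow(bin), 1)
  expect_setequal(c(bin$interactor_a, bin$interactor_b), c("A", "B"))
  expect_equal(bin$source_dataset, "IntAct")

  # 3 participants, no bait: all-versus-all gives choose(3,2) = 3 pairs
  tri <- parse_psimi25(psimi_doc(c("A", "B", "C")))
  expect_equal(nrow(tri), 3)
  pairs <- apply(cbind(tri$interactor_a, tri$interactor_b), 1,
                 function(x) paste(sort(x), collapse = "-"))
  expect_setequal(pairs, c("A-B", "A-C", "B-C"))

  # 3 participants with a bait: bait-versus-prey gives 2 pairs from the bait
  bait <- parse_psimi25(psimi_doc(c("A", "B", "C"), roles = c("", "bait", "")))
  expect_equal(nrow(bait), 2)
  expect_true(all(bait$interactor_a == "B"))

  # same pair from two dataset files stays two records with distinct sources
  two <- rbind(parse_psimi25(psimi_doc(c("A", "B"), datasets = "IntAct")),
               parse_psimi25(psimi_doc(c("A", "B"), datasets = "MINT")))
  expect_equal(sort(two$source_dataset), c("IntAct", "MINT"))

  expect_error(parse_psimi25(psimi_doc(character(0))), class = "wh_parse_error")
})

test_that("DrugBank XML parsing: targets optional, id mandatory", {
  xml <- '<drugbank>
    <drug><drugbank-id>DB00739</drugbank-id><name>Hetacillin</name><description>d</description>
      <targets><target><polypeptide id="PBPA_STRR6"/></target>
               <target><polypeptide id="PBP2_STRR6"/></target></targets></drug>
    <drug><drugbank-id>DB09004</drugbank-id><name>None</name><description></description><targets/></drug>
  </drugbank>'
  d <- parse_drugbank_xml(xml)
  expect_equal(d$target_accessions[[1]], c("PBPA_STRR6", "PBP2_STRR6"))
  expect_equal(d$target_accessions[[2]], character(0))
  expect_error(parse_drugbank_xml("<drugbank><drug><name>x</name></drug></drugbank>"),
               class = "wh_parse_error")
})

test_that("KEGG flat parsing: pathways, enzymes, optional /// at EOF", {
  path_txt <- paste(c(
    "ENTRY       spr00550            Pathway",
    "NAME        Peptidoglycan biosynthesis",
    "ORGANISM    Streptococcus pneumoniae R6 [TAX:171101]",
    "MEMBER      PBPA_STRR6",
    "            PBP2_STRR6",
    "///",
    "ENTRY       eco00550            Pathway",
    "NAME        Peptidoglycan biosynthesis",
    "ORGANISM    Escherichia coli [TAX:511145]",
    "MEMBER      MRDA_ECOLI"), collapse = "\n")  # no final ///: EOF terminates
  p <- parse_kegg_flat(path_txt, "pathway")
  expect_equal(nrow(p), 2)
  expect_equal(p$kegg_id, c("spr00550", "eco00550"))
  expect_equal(p$map_number, c("00550", "00550"))
  expect_equal(p$organism_tax_id, c(171101L, 511145L))
  expect_equal(p$member_accessions[[1]], c("PBPA_STRR6", "PBP2_STRR6"))

  enz <- parse_kegg_flat(paste(c(
    "ENTRY       EC 3.5.2.6            Enzyme",
    "NAME        beta-lactamase",
    "            penicillinase",
    "PROTEIN     AMPC_ECOLI",
    "///"), collapse = "\n"), "enzyme")
  expect_equal(enz$ec_number, "3.5.2.6")
  expect_equal(enz$names[[1]], c("beta-lactamase", "penicillinase"))

  expect_error(parse_kegg_flat("NAME        orphan\n///", "pathway"),
               class = "wh_parse_error")
})

test_that("OBO-XML parsing builds transitive parent chains", {
  xml <- '<obo>
    <term><id>GO:1</id><name>c</name><namespace>bp</namespace><is_a>GO:2</is_a></term>
    <term><id>GO:2</id><name>b</name><namespace>bp</namespace><is_a>GO:3</is_a></term>
    <term><id>GO:3</id><name>a</name><namespace>bp</namespace></term>
  </obo>'
  t <- parse_obo_xml(xml)
  expect_equal(nrow(t), 3)
  # hand transitive closure: GO:3 reachable from GO:1 via GO:2
  parents <- setNames(t$is_a_parents, t$term_id)
  reach <- parents[["GO:1"]]
  reach <- union(reach, unlist(parents[reach]))
  expect_true("GO:3" %in% reach)

  expect_error(parse_obo_xml("<obo><term><name>x</name></term></obo>"),
               class = "wh_parse_error")
  expect_error(parse_obo_xml("<obo><term><id>GO:1</id></term><term><id>GO:1</id></term></obo>"),
               class = "wh_parse_error")
})

test_that("the loader is transactional: failures leave the store untouched", {
  store <- new_store()
  nodes <- tempfile(); names_ <- tempfile()
  writeLines(sprintf("%d\t|\t%d\t|\tno rank\t|", 1:10, c(1L, 1:9)), nodes)
  writeLines(sprintf("%d\t|\tnode %d\t|\t\t|\tscientific name\t|", 1:10, 1:10), names_)
  rep1 <- quiet(wh_load(store, c(nodes, names_), "taxdump"))
  expect_equal(rep1$records_read, 10L)
  expect_equal(rep1$records_loaded, 10L)
  expect_null(rep1$failure)

  # error midway through the names file: nothing may load
  store2 <- new_store()
  writeLines(c(sprintf("%d\t|\tnode %d\t|\t\t|\tscientific name\t|", 1:6, 1:6),
               "99\t|\tghost\t|\t\t|\tsynonym\t|",
               sprintf("%d\t|\tnode %d\t|\t\t|\tscientific name\t|", 8:10, 8:10)),
             names_)
  rep2 <- quiet(wh_load(store2, c(nodes, names_), "taxdump"))
  expect_false(is.null(rep2$failure))
  expect_equal(rep2$records_loaded, 0L)
  expect_equal(unname(wh_counts(store2)["taxonomy"]), 0L)

  # loading the same file twice: duplicate natural keys reject the batch
  writeLines(sprintf("%d\t|\tnode %d\t|\t\t|\tscientific name\t|", 1:10, 1:10), names_)
  before <- wh_get(store, "taxonomy")
  rep3 <- quiet(wh_load(store, c(nodes, names_), "taxdump"))
  expect_false(is.null(rep3$failure))
  expect_identical(wh_get(store, "taxonomy"), before)
  wh_disconnect(store); wh_disconnect(store2)
})

test_that("any subset of source types yields a queryable store", {
  spec <- paper_spec()
  dir <- tempfile()
  manifest <- write_sources(spec, dir)
  # load only drugs + proteins: drug search and links still work
  store <- new_store()
  on.exit(wh_disconnect(store))
  for (i in which(manifest$format %in% c("uniprot", "drugbank")))
    quiet(wh_load(store, manifest$path[i], manifest$format[i]))
  quiet(resolve_crossrefs(store))
  expect_equal(search_drug(store, "Hetacillin")$drugbank_id, "DB00739")
  expect_equal(nrow(linked(store, "protein", "Q8DR59", "drug")), 9)
})
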