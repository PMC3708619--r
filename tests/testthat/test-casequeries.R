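# Worked multi-database queries: chromosomal neighborhood, ortholog scan,
# region scan.

test_that("the +/-10 gene neighborhood of spr0328 finds exactly gene 934791", {
  store <- paper_store()
  hits <- neighborhood_drug_targets(store, "spr0328", 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene_id, 934791L)
  expect_equal(hits$locus_tag, "spr0329")
  expect_equal(hits$protein_accession, "Q8DR59")
  expect_equal(hits$offset, 1L)
  expect_equal(length(hits$drugs[[1]]), 9)

  # k = 0: only the query gene itself could qualify; spr0328 is not a target
  expect_equal(nrow(neighborhood_drug_targets(store, "spr0328", 0)), 0)
  # gene without a PTT entry is a lookup error
  expect_error(neighborhood_drug_targets(store, "b0635", 10),
               class = "wh_usage_error")
  # query by GeneID works like the locus tag
  expect_equal(neighborhood_drug_targets(store, 934790, 10)$gene_id, 934791L)
})

test_that("k = Inf recovers every drug-target gene on the replicon", {
  store <- paper_store()
  allhits <- neighborhood_drug_targets(store, "spr0328", Inf)
  # the R6 replicon carries exactly two target genes: spr0329 and spr1800
  expect_setequal(allhits$locus_tag, c("spr0329", "spr1800"))
})

test_that("neighborhood hits equal the oracle scan on random worlds, monotone in k", {
  for (seed in c(61, 62)) {
    spec <- random_world(seed, sizes = list(genes = 40, proteins = 35,
                                            drugs = 10))
    store <- loaded_store(spec)
    with_ptt <- spec$ptt$locus_tag
    for (locus in with_ptt[c(1, 10, 20)]) {
      prev <- character(0)
      for (k in c(2, 5, 1000)) {
        got <- neighborhood_drug_targets(store, locus, k)
        want <- oracle_neighborhood(spec, locus, k)
        expect_setequal(got$locus_tag, want$locus_tag)
        if (nrow(got)) {
          ord <- order(got$locus_tag); ordw <- order(want$locus_tag)
          expect_equal(got$gene_id[ord], want$gene_id[ordw])
          expect_equal(got$offset[ord], want$offset[ordw])
        }
        # enlarging k never removes hits
        expect_true(all(prev %in% got$locus_tag))
        prev <- got$locus_tag
      }
    }
    wh_disconnect(store)
  }
})

test_that("the Streptococcus ortholog scan finds genes 934791 and 930269", {
  store <- paper_store()
  hits <- ortholog_neighborhood_scan(store, "spr0328", 1301, 10)
  expect_setequal(hits$gene_id, c(934791L, 930269L))
  tigr4 <- hits[hits$gene_id == 930269L, ]
  expect_match(tigr4$organism, "TIGR4")
  # degenerate subtree: the query gene's own strain reduces to the plain scan
  own <- ortholog_neighborhood_scan(store, "spr0328", 171101, 10)
  expect_equal(own$gene_id, neighborhood_drug_targets(store, "spr0328", 10)$gene_id)
  # protein in no cluster -> warning and empty result
  expect_warning(res <- ortholog_neighborhood_scan(store, "spr1800", 1301, 10),
                 "no UniRef cluster")
  expect_equal(nrow(res), 0)
})

test_that("ortholog scans equal per-member oracle neighborhood scans", {
  for (seed in c(71, 72)) {
    spec <- random_world(seed, sizes = list(genes = 40, proteins = 35,
                                            clusters = 6, drugs = 10))
    store <- loaded_store(spec)
    root <- spec$taxonomy$tax_id[1]
    pm <- oracle_primary_map(spec)
    # pick the first clustered protein that has a gene with a PTT row
    cand <- NULL
    for (i in seq_len(nrow(spec$uniref))) {
      for (acc in spec$uniref$member_accessions[[i]]) {
        prot <- which(spec$protein$primary_accession == unname(pm[toupper(acc)]))
        loci <- spec$protein$gene_locus_tags[[prot]]
        if (length(loci) && loci[1] %in% spec$ptt$locus_tag) {
          cand <- list(locus = loci[1], cluster = i); break
        }
      }
      if (!is.null(cand)) break
    }
    if (is.null(cand)) next
    got <- quiet(ortholog_neighborhood_scan(store, cand$locus, root, 5))
    # oracle: union of neighborhood scans around every cluster member's gene
    subtree <- oracle_subtree(spec, root)
    members <- spec$uniref$member_accessions[[cand$cluster]]
    want <- data.frame(gene_id = integer(0), locus_tag = character(0))
    for (acc in members) {
      prot <- which(spec$protein$primary_accession == unname(pm[toupper(acc)]))
      if (!spec$protein$tax_id[prot] %in% subtree) next
      for (locus in spec$protein$gene_locus_tags[[prot]]) {
        if (!locus %in% spec$ptt$locus_tag) next
        want <- rbind(want, oracle_neighborhood(spec, locus, 5)[, c("gene_id", "locus_tag")])
      }
    }
    want <- want[!duplicated(want$gene_id), , drop = FALSE]
    expect_setequal(got$gene_id, want$gene_id)
    wh_disconnect(store)
  }
})

test_that("region scan reports the TIGR4 target pair within 5000 bp", {
  store <- paper_store()
  hits <- region_scan(store, 1301, 5000, 2)
  expect_equal(nrow(hits), 1)
  expect_setequal(hits$gene_ids[[1]], c(930802L, 930805L))
  expect_true(hits$span_bp <= 5000)
  expect_match(hits$organism, "TIGR4")
  # a replicon whose only target gene count is below min_targets yields no hit
  expect_equal(nrow(region_scan(store, 171101, 5000, 2)), 0)
})

test_that("region scans equal the quadratic oracle and grow monotonically", {
  for (seed in c(81, 82)) {
    spec <- random_world(seed, sizes = list(genes = 40, proteins = 35,
                                            drugs = 12))
    store <- loaded_store(spec)
    root <- spec$taxonomy$tax_id[1]
    sets_for <- function(hits) lapply(hits$gene_ids, sort)
    prev <- list()
    for (max_len in c(3000, 8000, 20000)) {
      got <- region_scan(store, root, max_len, 2)
      want <- oracle_region_scan(spec, root, max_len, 2)
      expect_setequal(vapply(sets_for(got), paste, "", collapse = ","),
                      vapply(want, function(w) paste(w$gene_ids, collapse = ","),
                             ""))
      # monotonicity: every smaller-window hit survives inside some hit
      for (p in prev) {
        expect_true(any(vapply(sets_for(got), function(s) all(p %in% s),
                               logical(1))))
      }
      prev <- sets_for(got)
    }
    wh_disconnect(store)
  }
})

test_that("region hits are invariant under shuffled PTT row order", {
  spec <- paper_spec()
  shuffled <- spec
  set.seed(5)
  shuffled$ptt <- shuffled$ptt[sample(nrow(shuffled$ptt)), ]
  store <- loaded_store(shuffled)
  on.exit(wh_disconnect(store))
  hits <- region_scan(store, 1301, 5000, 2)
  expect_equal(nrow(hits), 1)
  expect_setequal(hits$gene_ids[[1]], c(930802L, 930805L))
})

test_that("the map-level pathway view of Hetacillin spans three organisms", {
  store <- paper_store()
  orgs <- drug_pathway_organisms(store, "DB00739")
  expect_setequal(orgs$organism_tax_id, c(171101L, 511145L, 195102L))
  expect_true(all(orgs$map_number == "00550"))
})

test_that("printed-fact results are stable across repeated runs", {
  store <- paper_store()
  first <- neighborhood_drug_targets(store, "spr0328", 10)
  for (i in 1:25) {
    expect_identical(neighborhood_drug_targets(store, "spr0328", 10), first)
  }
  s1 <- ortholog_neighborhood_scan(store, "spr0328", 1301, 10)
  s2 <- ortholog_neighborhood_scan(store, "spr0328", 1301, 10)
  expect_identical(s1, s2)
})
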