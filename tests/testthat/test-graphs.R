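# Graph construction, weighting, metrics and neighbor classification.

test_that("taxonomy graph: chain arithmetic, leaf roots, tree invariants", {
  store <- new_store()
  on.exit(wh_disconnect(store))
  wh_insert(store, "taxonomy", chain_taxa(6))
  g <- taxonomy_graph(store, 1)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  leaf <- taxonomy_graph(store, 6)
  expect_equal(igraph::vcount(leaf), 1)
  expect_equal(igraph::ecount(leaf), 0)
  expect_error(taxonomy_graph(store, 999), class = "wh_usage_error")
})

test_that("taxonomy subtrees are rooted acyclic trees with full reachability", {
  for (seed in c(31, 32)) {
    spec <- random_world(seed, sizes = list(taxa = 15))
    store <- loaded_store(spec)
    for (root in spec$taxonomy$tax_id) {
      g <- taxonomy_graph(store, root)
      expect_equal(igraph::ecount(g), igraph::vcount(g) - 1)
      expect_true(igraph::is_dag(g))
      d <- igraph::distances(g, v = paste0("taxonomy:", root), mode = "out")
      expect_true(all(is.finite(d)))
      # matches the oracle subtree from the spec's parent table
      expect_setequal(as.integer(igraph::V(g)$key), oracle_subtree(spec, root))
    }
    wh_disconnect(store)
  }
})

test_that("PPI edge weights count distinct reporting datasets", {
  store <- new_store()
  on.exit(wh_disconnect(store))
  wh_insert(store, "protein", data.frame(
    primary_accession = c("A", "B", "C"), accessions = I(list("A", "B", "C")),
    name = "p", sequence = "MK", tax_id = 1L,
    gene_locus_tags = I(replicate(3, character(0), simplify = FALSE))))
  wh_insert(store, "interaction", data.frame(
    source_dataset = c("IntAct", "MINT", "IntAct", "IntAct", "IntAct"),
    interactor_a = c("A", "A", "A", "A", "C"),
    interactor_b = c("B", "B", "B", "C", "C"),
    detection_method = c("y2h", "y2h", "pulldown", "y2h", "y2h"),
    pubmed_id = as.character(1:5)))
  g <- ppi_graph(store)
  w <- setNames(igraph::E(g)$weight, attr(igraph::E(g), "vnames"))
  # {A,B}: IntAct + MINT -> 2 (the second IntAct report adds nothing)
  expect_equal(unname(w["protein:A|protein:B"]), 2)
  # {A,C}: one dataset -> 1
  expect_equal(unname(w["protein:A|protein:C"]), 1)
  # the C-C self-interaction is kept as data but yields no edge
  expect_equal(igraph::ecount(g), 2)
  expect_true("protein:C" %in% igraph::V(g)$name)
})

test_that("PPI weights on random worlds equal a brute-force group-by, within dataset bounds", {
  for (seed in c(41, 42)) {
    spec <- random_world(seed, sizes = list(interactions = 30, datasets = 3))
    store <- loaded_store(spec)
    g <- ppi_graph(store)
    oracle <- oracle_ppi_weights(spec)
    el <- igraph::as_edgelist(g)
    got <- data.frame(
      a = pmin(sub("^protein:", "", el[, 1]), sub("^protein:", "", el[, 2])),
      b = pmax(sub("^protein:", "", el[, 1]), sub("^protein:", "", el[, 2])),
      weight = igraph::E(g)$weight)
    got <- got[order(got$a, got$b), ]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
    n_ds <- length(unique(spec$interaction$source_dataset))
    if (nrow(got)) expect_true(all(got$weight >= 1 & got$weight <= n_ds))
    wh_disconnect(store)
  }
})

test_that("drug-pathway edges weight the target/member intersection", {
  store <- paper_store()
  g <- drug_pathway_graph(store)
  # |{PBPA_STRR6, PBP2_STRR6} n members(spr00550)| = 2, enumerated by hand
  eid <- igraph::get_edge_ids(g, c("drug:DB00739", "pathway:spr00550"))
  expect_gt(eid, 0)
  expect_equal(igraph::E(g)$weight[eid], 2L)
  # a drug with no targets is an isolated vertex
  expect_equal(igraph::degree(g, "drug:DB09004"), c("drug:DB09004" = 0))
  # full edge set equals the brute-force double loop
  oracle <- oracle_dp_edges(paper_spec())
  el <- igraph::as_edgelist(g)
  got <- data.frame(drug = sub("^drug:", "", el[, 1]),
                    pathway = sub("^pathway:", "", el[, 2]),
                    weight = as.integer(igraph::E(g)$weight))
  got <- got[order(got$drug, got$pathway), ]
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("metrics match hand arithmetic and a BFS oracle", {
  chain <- igraph::make_graph(~ a - b - c - d - e - f)
  m <- graph_metrics(chain)
  expect_equal(m$diameter, 5L)
  expect_equal(m$connected_components, 1L)

  two <- igraph::make_graph(~ a - b, c - d)
  expect_equal(graph_metrics(two)$connected_components, 2L)

  empty <- igraph::make_empty_graph(0)
  expect_equal(graph_metrics(empty),
               list(vertex_count = 0L, edge_count = 0L, diameter = 0L,
                    max_degree = 0L, connected_components = 0L))

  # random 20-vertex graph vs all-pairs BFS oracle
  set.seed(99)
  g <- igraph::sample_gnp(20, 0.15)
  igraph::V(g)$name <- sprintf("v%02d", 1:20)
  m <- graph_metrics(g)
  o <- oracle_metrics(igraph::V(g)$name, igraph::as_edgelist(g))
  expect_equal(m$diameter, o$diameter)
  expect_equal(m$connected_components, o$connected_components)
  expect_equal(m$max_degree, o$max_degree)
})

test_that("shortest paths are minimum-hop with lexicographic tie-breaks", {
  g <- igraph::make_graph(~ a - b - c, a - d - c)
  expect_equal(graph_shortest_path(g, "a", "a"), "a")
  # two 2-hop routes a-b-c and a-d-c: the lexicographically smaller wins
  expect_equal(graph_shortest_path(g, "a", "c"), c("a", "b", "c"))
  chain <- igraph::make_graph(~ a - b - c)
  expect_equal(graph_shortest_path(chain, "a", "c"), c("a", "b", "c"))
  disc <- igraph::make_graph(~ a - b, c - d)
  expect_equal(graph_shortest_path(disc, "a", "c"), character(0))
  expect_error(graph_shortest_path(g, "a", "zz"), class = "wh_usage_error")

  # lengths equal a BFS oracle on a random graph
  set.seed(7)
  rg <- igraph::sample_gnp(15, 0.2)
  igraph::V(rg)$name <- sprintf("v%02d", 1:15)
  o <- oracle_metrics(igraph::V(rg)$name, igraph::as_edgelist(rg))
  adj_dist <- igraph::distances(rg)
  for (pair in list(c(1, 5), c(2, 14), c(3, 9))) {
    p <- graph_shortest_path(rg, sprintf("v%02d", pair[1]), sprintf("v%02d", pair[2]))
    want <- adj_dist[pair[1], pair[2]]
    if (is.finite(want)) expect_equal(length(p) - 1, unname(want))
    else expect_equal(p, character(0))
  }
})

test_that("drug neighbor classification partitions the printed world correctly", {
  store <- paper_store()
  nb <- drug_neighbors(store, "DB00739")
  # sharing a target protein -> target neighbors (8 other drugs on Q8DR59)
  expect_equal(length(nb$target_neighbors), 8)
  expect_true("DB00713" %in% nb$target_neighbors)
  # Ceftazidime and Cyclacillin act on map-00550 pathways of other organisms
  expect_true(all(c("DB00438", "DB01000") %in% nb$pathway_neighbors))
  # the partition covers every other target-bearing drug exactly once
  all_classes <- c(nb$target_neighbors, nb$pathway_neighbors,
                   nb$distant_neighbors$drugbank_id, nb$unreachable)
  expect_false(anyDuplicated(all_classes) > 0)
  spec <- paper_spec()
  with_targets <- spec$drug$drugbank_id[lengths(spec$drug$target_accessions) > 0]
  expect_setequal(all_classes, setdiff(with_targets, "DB00739"))
  expect_error(drug_neighbors(store, "DB99999"), class = "wh_usage_error")
})

test_that("drug neighbor partitions equal the set-algebra oracle on random worlds", {
  for (seed in c(51, 52)) {
    spec <- random_world(seed, sizes = list(drugs = 10, pathways = 8))
    store <- loaded_store(spec)
    with_targets <- spec$drug$drugbank_id[
      vapply(spec$drug$target_accessions, function(t) {
        pm <- oracle_primary_map(spec)
        any(!is.na(pm[toupper(t)]))
      }, logical(1))]
    for (qid in utils::head(with_targets, 3)) {
      got <- drug_neighbors(store, qid)
      want <- oracle_drug_neighbors(spec, qid)
      expect_equal(got$target_neighbors, want$target_neighbors)
      expect_equal(got$pathway_neighbors, want$pathway_neighbors)
      expect_equal(setNames(got$distant_neighbors$distance,
                            got$distant_neighbors$drugbank_id)[
                              order(names(setNames(got$distant_neighbors$distance,
                                                   got$distant_neighbors$drugbank_id)))],
                   want$distant[order(names(want$distant))])
      expect_equal(got$unreachable, want$unreachable)
    }
    wh_disconnect(store)
  }
})

test_that("graph export writes GraphML and TSV edge lists", {
  store <- paper_store()
  g <- drug_pathway_graph(store)
  gm <- tempfile(fileext = ".graphml")
  graph_export(g, gm, "graphml")
  expect_true(file.size(gm) > 0)
  back <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  tsv <- tempfile(fileext = ".tsv")
  graph_export(g, tsv, "tsv")
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), igraph::ecount(g))
})
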