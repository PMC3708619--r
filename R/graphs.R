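# Entity graphs over the warehouse: taxonomy trees, evidence-weighted
# protein-protein interaction networks, and drug-pathway bipartite graphs.
#
# Graphs are igraph objects whose vertex names are "kind:natural-key"
# (guaranteeing uniqueness across kinds in one graph) with `kind` and `key`
# vertex attributes.  Edge weights are evidence counts (>= 1), never
# lengths: all distances in this package are hop counts.  Self-loops are
# excluded from edges by construction.

wh_vertex_name <- function(kind, key) paste(kind, key, sep = ":")

#' Build the taxonomy tree below a root
#'
#' Directed graph (parent to child) of the root and all of its descendants,
#' built by recursive descent over the stored parent links.
#'
#' @param store A `wh_store`.
#' @param root_tax_id Tax id of the subtree root; must be loaded.
#' @return A directed igraph; for a loaded tree, `|E| = |V| - 1`.
#' @export
taxonomy_graph <- function(store, root_tax_id) {
  taxa <- wh_query(store, "SELECT TaxId, ParentTaxId FROM Taxonomy")
  root_tax_id <- as.integer(root_tax_id)
  if (!root_tax_id %in% taxa$TaxId)
    wh_usage_stop(sprintf("tax_id %d is not loaded", root_tax_id))
  kids <- split(taxa$TaxId, taxa$ParentTaxId)
  vertices <- integer(0)
  edges_from <- integer(0)
  edges_to <- integer(0)
  stack <- root_tax_id
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    vertices <- c(vertices, cur)
    children <- setdiff(kids[[as.character(cur)]] %||% integer(0), cur)
    if (length(children)) {
      children <- sort(children)
      edges_from <- c(edges_from, rep(cur, length(children)))
      edges_to <- c(edges_to, children)
      stack <- c(stack, rev(children))
    }
  }
  vn <- wh_vertex_name("taxonomy", vertices)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(vn), name = vn, kind = "taxonomy",
                            key = as.character(vertices))
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(wh_vertex_name("taxonomy", edges_from),
                                    wh_vertex_name("taxonomy", edges_to)))
  g
}

# Tax ids of a subtree (root included); scope helper for other builders.
wh_subtree_taxids <- function(store, root_tax_id) {
  g <- taxonomy_graph(store, root_tax_id)
  as.integer(igraph::vertex_attr(g, "key"))
}

#' Build the protein-protein interaction graph
#'
#' Undirected and weighted: one edge per unordered protein pair with at
#' least one stored interaction whose both interactors resolve to loaded
#' proteins; the weight is the number of DISTINCT source datasets reporting
#' that pair (repeated reports within one dataset do not add weight).
#' Self-interactions are kept in the data but excluded from edges.  Vertex
#' keys are primary accessions.
#'
#' @param store A `wh_store`.
#' @param scope Optional restriction: a single tax id (the subtree below it)
#'   or a vector of protein accessions.
#' @return An undirected weighted igraph.
#' @export
ppi_graph <- function(store, scope = NULL) {
  rows <- wh_query(store,
    "SELECT i.SourceDataset AS ds, pa.Protein_WID AS wa, pb.Protein_WID AS wb
     FROM Interaction i
     JOIN ProteinAccessionNumber pa ON UPPER(pa.AccessionNumber) = UPPER(i.InteractorA)
     JOIN ProteinAccessionNumber pb ON UPPER(pb.AccessionNumber) = UPPER(i.InteractorB)")
  prot <- wh_query(store,
    "SELECT p.WID AS wid, p.TaxId AS tax, a.AccessionNumber AS acc
     FROM Protein p JOIN ProteinAccessionNumber a ON a.Protein_WID = p.WID AND a.Position = 0")
  primary <- stats::setNames(prot$acc, prot$wid)
  keep_wids <- prot$wid
  if (!is.null(scope)) {
    if (is.numeric(scope) && length(scope) == 1) {
      taxids <- wh_subtree_taxids(store, scope)
      keep_wids <- prot$wid[prot$tax %in% taxids]
    } else {
      keep_wids <- prot$wid[toupper(prot$acc) %in% toupper(as.character(scope))]
    }
  }
  rows <- rows[rows$wa %in% keep_wids & rows$wb %in% keep_wids, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  verts <- sort(unique(c(rows$wa, rows$wb)))
  pairs <- rows[rows$wa != rows$wb, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts),
                            name = wh_vertex_name("protein", primary[as.character(verts)]),
                            kind = "protein", key = unname(primary[as.character(verts)]))
  if (nrow(pairs) > 0) {
    a <- pmin(pairs$wa, pairs$wb)
    b <- pmax(pairs$wa, pairs$wb)
    key <- paste(a, b)
    w <- vapply(split(pairs$ds, key), function(d) length(unique(d)), integer(1))
    uk <- names(w)
    ua <- as.integer(sub(" .*", "", uk))
    ub <- as.integer(sub(".* ", "", uk))
    g <- igraph::add_edges(g,
      rbind(wh_vertex_name("protein", primary[as.character(ua)]),
            wh_vertex_name("protein", primary[as.character(ub)])),
      weight = unname(w))
  }
  g
}

#' Build the drug-pathway bipartite graph
#'
#' Undirected, weighted and bipartite: vertices are every loaded drug and
#' pathway; an edge joins drug d and pathway p when at least one protein is
#' both a target of d and a member of p, weighted by the number of such
#' proteins.  Requires resolved cross-references.
#'
#' @param store A `wh_store`.
#' @return An undirected weighted igraph with a `type` vertex attribute
#'   (TRUE for pathways).
#' @export
drug_pathway_graph <- function(store) {
  drugs <- wh_query(store, "SELECT WID, DrugBankId FROM Drug ORDER BY WID")
  paths <- wh_query(store, "SELECT WID, KeggId FROM Pathway ORDER BY WID")
  edges <- wh_query(store,
    "SELECT d.DrugBankId AS d, pw.KeggId AS p, COUNT(DISTINCT dp.Protein_WID) AS w
     FROM Drug_has_Protein dp
     JOIN Pathway_has_Protein pp ON pp.Protein_WID = dp.Protein_WID
     JOIN Drug d ON d.WID = dp.Drug_WID
     JOIN Pathway pw ON pw.WID = pp.Pathway_WID
     GROUP BY d.DrugBankId, pw.KeggId")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(drugs),
                            name = wh_vertex_name("drug", drugs$DrugBankId),
                            kind = "drug", key = drugs$DrugBankId, type = FALSE)
  g <- igraph::add_vertices(g, nrow(paths),
                            name = wh_vertex_name("pathway", paths$KeggId),
                            kind = "pathway", key = paths$KeggId, type = TRUE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(wh_vertex_name("drug", edges$d),
                                    wh_vertex_name("pathway", edges$p)),
                           weight = as.integer(edges$w))
  g
}

#' Graph metrics
#'
#' Vertex and edge counts, maximum degree, number of connected components,
#' and the diameter measured as the longest shortest path within the
#' largest component, ignoring edge direction and weights (hop count).
#'
#' @param g An igraph.
#' @return List with `vertex_count`, `edge_count`, `diameter`, `max_degree`,
#'   `connected_components`; all zero for the empty graph.
#' @export
graph_metrics <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0)
    return(list(vertex_count = 0L, edge_count = 0L, diameter = 0L,
                max_degree = 0L, connected_components = 0L))
  ug <- igraph::as_undirected(g, mode = "collapse")
  comp <- igraph::components(ug)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(ug, which(comp$membership == big))
  diam <- if (igraph::vcount(sub) == 1) 0L
          else as.integer(igraph::diameter(sub, directed = FALSE, weights = NA))
  list(vertex_count = n,
       edge_count = igraph::ecount(g),
       diameter = diam,
       max_degree = as.integer(max(igraph::degree(ug))),
       connected_components = as.integer(comp$no))
}

#' Minimum-hop path between two vertices
#'
#' Breadth-first shortest path ignoring direction and weights.  Among all
#' minimum-hop paths the lexicographically smallest vertex-name sequence is
#' returned, so the result is deterministic.  Returns `character(0)` when
#' the vertices are disconnected; the one-vertex path when `v1 == v2`.
#'
#' @param g An igraph.
#' @param v1,v2 Vertex names (`"kind:key"`).
#' @return Character vector of vertex names along the path.
#' @export
graph_shortest_path <- function(g, v1, v2) {
  vn <- igraph::V(g)$name
  if (!v1 %in% vn || !v2 %in% vn)
    wh_usage_stop("unknown vertex")
  if (identical(v1, v2)) return(v1)
  adj <- wh_adjacency(g)
  d1 <- wh_bfs_dist(adj, v1)
  if (!is.finite(d1[[v2]])) return(character(0))
  d2 <- wh_bfs_dist(adj, v2)
  total <- d1[[v2]]
  path <- v1
  cur <- v1
  for (step in seq_len(total)) {
    nbrs <- adj[[cur]]
    ok <- nbrs[d1[nbrs] == step & d2[nbrs] == total - step]
    cur <- sort(ok)[1]
    path <- c(path, cur)
  }
  path
}

# Adjacency list (undirected view), neighbors sorted by name.
wh_adjacency <- function(g) {
  vn <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  adj <- stats::setNames(replicate(length(vn), character(0), simplify = FALSE), vn)
  if (nrow(el) > 0) {
    for (nm in vn) adj[[nm]] <- character(0)
    sp1 <- split(el[, 2], el[, 1])
    sp2 <- split(el[, 1], el[, 2])
    for (nm in names(sp1)) adj[[nm]] <- c(adj[[nm]], sp1[[nm]])
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

wh_bfs_dist <- function(adj, from) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[[from]] <- 0
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!is.finite(d[[w]])) { d[[w]] <- d[[v]] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

#' Classify the drug neighbors of a drug
#'
#' Partitions every other drug with at least one resolved protein target
#' into: `target_neighbors` (share at least one target protein with the
#' query), `pathway_neighbors` (not target neighbors, but some pathway
#' containing a target of each matches at map level, i.e. the
#' organism-independent 5-digit KEGG map number), `distant_neighbors`
#' (reachable from the query in the drug-pathway bipartite graph but
#' neither of the above, annotated with the bipartite hop distance), and
#' `unreachable`.  `nearest_distant` lists the distant neighbors at the
#' minimal hop distance.
#'
#' @param store A `wh_store` with resolved cross-references.
#' @param drugbank_id Query drug id.
#' @return List of the four classes (DrugBank ids, sorted) plus
#'   `distant_neighbors` as a data.frame with `drugbank_id` and `distance`,
#'   and `nearest_distant`.
#' @export
drug_neighbors <- function(store, drugbank_id) {
  q <- wh_lookup(store, "drug", drugbank_id)
  if (nrow(q) == 0)
    wh_usage_stop(sprintf("unknown drug %s", drugbank_id))
  qid <- q$drugbank_id[1]
  tgt <- wh_query(store,
    "SELECT d.DrugBankId AS id, dp.Protein_WID AS pw
     FROM Drug_has_Protein dp JOIN Drug d ON d.WID = dp.Drug_WID")
  targets_by_drug <- split(tgt$pw, tgt$id)
  pmaps <- wh_query(store,
    "SELECT pp.Protein_WID AS pw, p.MapNumber AS map
     FROM Pathway_has_Protein pp JOIN Pathway p ON p.WID = pp.Pathway_WID")
  maps_of <- function(pws) unique(pmaps$map[pmaps$pw %in% pws])
  q_targets <- targets_by_drug[[qid]] %||% integer(0)
  q_maps <- maps_of(q_targets)
  others <- setdiff(names(targets_by_drug), qid)
  target_n <- character(0); pathway_n <- character(0); rest <- character(0)
  for (d in others) {
    if (length(intersect(targets_by_drug[[d]], q_targets)) > 0) {
      target_n <- c(target_n, d)
    } else if (length(intersect(maps_of(targets_by_drug[[d]]), q_maps)) > 0) {
      pathway_n <- c(pathway_n, d)
    } else {
      rest <- c(rest, d)
    }
  }
  distant <- data.frame(drugbank_id = character(0), distance = integer(0))
  unreachable <- character(0)
  if (length(rest) > 0) {
    g <- drug_pathway_graph(store)
    d <- wh_bfs_dist(wh_adjacency(g), wh_vertex_name("drug", qid))
    dd <- d[wh_vertex_name("drug", rest)]
    reach <- is.finite(dd)
    distant <- data.frame(drugbank_id = rest[reach],
                          distance = as.integer(dd[reach]))
    distant <- distant[order(distant$distance, distant$drugbank_id), , drop = FALSE]
    rownames(distant) <- NULL
    unreachable <- sort(rest[!reach])
  }
  list(target_neighbors = sort(target_n),
       pathway_neighbors = sort(pathway_n),
       distant_neighbors = distant,
       nearest_distant = if (nrow(distant)) distant$drugbank_id[
         distant$distance == min(distant$distance)] else character(0),
       unreachable = unreachable)
}

#' Export a graph as GraphML or edge-list TSV
#'
#' @param g An igraph.
#' @param file Output path.
#' @param format `"graphml"` or `"tsv"` (edge list with weights).
#' @return The path, invisibly.
#' @export
graph_export <- function(g, file, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, file, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- if ("weight" %in% igraph::edge_attr_names(g))
      igraph::E(g)$weight else rep(1L, nrow(el))
    df <- data.frame(from = el[, 1], to = el[, 2], weight = w)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
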