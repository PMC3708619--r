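# Brute-force oracles computed straight from a fixture spec's relation
# tables, independent of the store, the SQL layer and igraph.

# accession (any case) -> primary accession, from the spec protein table
oracle_primary_map <- function(spec) {
  p <- spec$protein
  m <- character(0)
  for (i in seq_len(nrow(p)))
    m[toupper(p$accessions[[i]])] <- p$primary_accession[i]
  m
}

# PPI edge weights: distinct datasets per unordered resolved protein pair.
oracle_ppi_weights <- function(spec) {
  pm <- oracle_primary_map(spec)
  it <- spec$interaction
  a <- unname(pm[toupper(it$interactor_a)])
  b <- unname(pm[toupper(it$interactor_b)])
  keep <- !is.na(a) & !is.na(b) & a != b
  if (!any(keep)) return(data.frame(a = character(0), b = character(0),
                                    weight = integer(0)))
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  ds <- it$source_dataset[keep]
  key <- paste(lo, hi, sep = "\r")
  w <- vapply(split(ds, key), function(d) length(unique(d)), integer(1))
  out <- data.frame(a = sub("\r.*", "", names(w)), b = sub(".*\r", "", names(w)),
                    weight = unname(w))
  out[order(out$a, out$b), , drop = FALSE]
}

# drug-pathway edges: |targets(d) n members(p)| over resolved proteins.
oracle_dp_edges <- function(spec) {
  pm <- oracle_primary_map(spec)
  resolve <- function(accs) unique(pm[toupper(accs)][!is.na(pm[toupper(accs)])])
  out <- data.frame(drug = character(0), pathway = character(0),
                    weight = integer(0))
  for (i in seq_len(nrow(spec$drug))) {
    tg <- resolve(spec$drug$target_accessions[[i]])
    for (j in seq_len(nrow(spec$pathway))) {
      w <- length(intersect(tg, resolve(spec$pathway$member_accessions[[j]])))
      if (w > 0)
        out <- rbind(out, data.frame(drug = spec$drug$drugbank_id[i],
                                     pathway = spec$pathway$kegg_id[j],
                                     weight = w))
    }
  }
  out[order(out$drug, out$pathway), , drop = FALSE]
}

# plain queue BFS distances over the bipartite drug/pathway world
oracle_dp_distances <- function(spec, from_drug) {
  edges <- oracle_dp_edges(spec)
  nodes <- c(paste0("d|", spec$drug$drugbank_id),
             paste0("p|", spec$pathway$kegg_id))
  adj <- setNames(replicate(length(nodes), character(0), simplify = FALSE), nodes)
  for (i in seq_len(nrow(edges))) {
    d <- paste0("d|", edges$drug[i]); p <- paste0("p|", edges$pathway[i])
    adj[[d]] <- c(adj[[d]], p); adj[[p]] <- c(adj[[p]], d)
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  start <- paste0("d|", from_drug)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(dist[w])) {
      dist[w] <- dist[v] + 1
      queue <- c(queue, w)
    }
  }
  dist
}

# drug-neighbor partition by set algebra on the spec tables
oracle_drug_neighbors <- function(spec, qid) {
  pm <- oracle_primary_map(spec)
  resolve <- function(accs) unique(pm[toupper(accs)][!is.na(pm[toupper(accs)])])
  targets <- lapply(seq_len(nrow(spec$drug)),
                    function(i) resolve(spec$drug$target_accessions[[i]]))
  names(targets) <- spec$drug$drugbank_id
  maps_of <- function(tg) {
    hit <- vapply(seq_len(nrow(spec$pathway)), function(j)
      length(intersect(tg, resolve(spec$pathway$member_accessions[[j]]))) > 0,
      logical(1))
    unique(spec$pathway$map_number[hit])
  }
  with_targets <- names(targets)[lengths(targets) > 0]
  qt <- targets[[qid]]
  qm <- maps_of(qt)
  others <- setdiff(with_targets, qid)
  tn <- others[vapply(others, function(d) length(intersect(targets[[d]], qt)) > 0,
                      logical(1))]
  rest1 <- setdiff(others, tn)
  pn <- rest1[vapply(rest1, function(d) length(intersect(maps_of(targets[[d]]), qm)) > 0,
                     logical(1))]
  rest2 <- setdiff(rest1, pn)
  dist <- oracle_dp_distances(spec, qid)
  dd <- dist[paste0("d|", rest2)]
  list(target_neighbors = sort(tn), pathway_neighbors = sort(pn),
       distant = setNames(as.integer(dd[is.finite(dd)]),
                          rest2[is.finite(dd)]),
       unreachable = sort(rest2[!is.finite(dd)]))
}

# drugs of a protein primary accession, from the spec drug table
oracle_drugs_of <- function(spec, primary) {
  pm <- oracle_primary_map(spec)
  hit <- vapply(spec$drug$target_accessions, function(t)
    primary %in% pm[toupper(t)], logical(1))
  sort(spec$drug$drugbank_id[hit])
}

# neighborhood scan by direct enumeration over the spec PTT table
oracle_neighborhood <- function(spec, locus, k) {
  pm <- oracle_primary_map(spec)
  row <- which(toupper(spec$ptt$locus_tag) == toupper(locus))
  stopifnot(length(row) == 1)
  rep_rows <- spec$ptt[spec$ptt$replicon_accession ==
                         spec$ptt$replicon_accession[row], , drop = FALSE]
  rep_rows <- rep_rows[order(rep_rows$start_bp, rep_rows$end_bp,
                             rep_rows$locus_tag), , drop = FALSE]
  idx <- which(toupper(rep_rows$locus_tag) == toupper(locus))
  lo <- max(1, idx - k); hi <- min(nrow(rep_rows), idx + k)
  hits <- data.frame(gene_id = integer(0), locus_tag = character(0),
                     offset = integer(0))
  for (i in lo:hi) {
    prim <- pm[toupper(rep_rows$pid[i])]
    if (is.na(prim)) next
    drugs <- oracle_drugs_of(spec, unname(prim))
    if (length(drugs) == 0) next
    gid <- spec$gene$gene_id[toupper(spec$gene$locus_tag) ==
                               toupper(rep_rows$locus_tag[i])]
    hits <- rbind(hits, data.frame(gene_id = gid[1],
                                   locus_tag = rep_rows$locus_tag[i],
                                   offset = i - idx))
  }
  hits
}

# tax ids below (and including) a root, by repeated parent scans
oracle_subtree <- function(spec, root) {
  t <- spec$taxonomy
  members <- root
  repeat {
    more <- t$tax_id[t$parent_tax_id %in% members & !t$tax_id %in% members]
    if (length(more) == 0) break
    members <- c(members, more)
  }
  members
}

# region scan: O(n^2) enumeration of index ranges, dropping contained ones
oracle_region_scan <- function(spec, root, max_len, min_targets) {
  pm <- oracle_primary_map(spec)
  subtree <- oracle_subtree(spec, root)
  out <- list()
  for (r in unique(spec$ptt$replicon_accession)) {
    rows <- spec$ptt[spec$ptt$replicon_accession == r, , drop = FALSE]
    taxs <- spec$gene$tax_id[match(toupper(rows$locus_tag),
                                   toupper(spec$gene$locus_tag))]
    tax <- taxs[!is.na(taxs)][1]
    if (is.na(tax) || !tax %in% subtree) next
    is_t <- vapply(rows$pid, function(p) {
      prim <- pm[toupper(p)]
      !is.na(prim) && length(oracle_drugs_of(spec, unname(prim))) > 0
    }, logical(1))
    tg <- rows[is_t, , drop = FALSE]
    tg <- tg[order(tg$start_bp, tg$end_bp), , drop = FALSE]
    n <- nrow(tg)
    if (n < min_targets) next
    wins <- list()
    for (i in seq_len(n)) for (j in i:n) {
      if (j - i + 1 < min_targets) next
      if (max(tg$end_bp[i:j]) - tg$start_bp[i] + 1 <= max_len)
        wins[[length(wins) + 1L]] <- c(i, j)
    }
    if (length(wins) == 0) next
    keep <- vapply(seq_along(wins), function(a) {
      !any(vapply(seq_along(wins), function(b) {
        b != a && wins[[b]][1] <= wins[[a]][1] && wins[[b]][2] >= wins[[a]][2]
      }, logical(1)))
    }, logical(1))
    for (w in wins[keep]) {
      gids <- spec$gene$gene_id[match(toupper(tg$locus_tag[w[1]:w[2]]),
                                      toupper(spec$gene$locus_tag))]
      out[[length(out) + 1L]] <- list(replicon = r, gene_ids = sort(gids))
    }
  }
  out
}

# all-pairs BFS metrics from an edge list + isolated vertex names
oracle_metrics <- function(vertices, edges) {
  adj <- setNames(replicate(length(vertices), character(0), simplify = FALSE),
                  vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(s) {
    d <- setNames(rep(Inf, length(vertices)), vertices)
    d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
    }
    d
  }
  comp_id <- setNames(rep(NA_integer_, length(vertices)), vertices)
  cid <- 0L
  for (v in vertices) if (is.na(comp_id[v])) {
    cid <- cid + 1L
    comp_id[names(bfs(v))[is.finite(bfs(v))]] <- cid
  }
  sizes <- table(comp_id)
  big <- names(sizes)[which.max(sizes)]
  bigv <- vertices[comp_id == big]
  diam <- 0
  for (v in bigv) {
    d <- bfs(v)
    diam <- max(diam, max(d[bigv][is.finite(d[bigv])]))
  }
  list(vertex_count = length(vertices),
       edge_count = nrow(edges),
       diameter = as.integer(diam),
       max_degree = if (length(adj)) max(vapply(adj, function(x)
         length(unique(x)), integer(1))) else 0L,
       connected_components = cid)
}

# ---- corruption injector --------------------------------------------------

# Apply one random, guaranteed-fatal corruption to a written source file.
corrupt_source <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  pick <- function(opts) opts[[sample.int(length(opts), 1)]]
  lines <- switch(format,
    taxdump_nodes = {  # nodes.dmp
      i <- sample.int(length(lines), 1)
      pick(list(
        function() { lines[i] <- "garbage row"; lines },
        function() { lines[i] <- "abc\t|\t1\t|\tno rank\t|"; lines }))()
    },
    taxdump_names = {
      c(lines, "999999999\t|\tghost name\t|\t\t|\tsynonym\t|")
    },
    gene_info = {
      body <- which(!startsWith(lines, "#"))
      i <- pick(as.list(body))
      f <- strsplit(lines[i], "\t")[[1]]
      f[2] <- "notanumber"
      lines[i] <- paste(f, collapse = "\t")
      lines
    },
    ptt = {
      i <- sample(4:length(lines), 1)
      f <- strsplit(lines[i], "\t")[[1]]
      f[1] <- pick(list("255..190", "nonsense", "10..x"))
      lines[i] <- paste(f, collapse = "\t")
      lines
    },
    uniprot = pick(list(
      function() gsub("(?s)<sequence>.*?</sequence>", "", paste(lines, collapse = "\n"), perl = TRUE),
      function() c(lines, "<unclosed>")))(),
    uniref = gsub("(?s)<representativeMember>.*?</representativeMember>", "",
                  paste(lines, collapse = "\n"), perl = TRUE),
    psimi = pick(list(
      function() gsub("<interactorRef>i1</interactorRef>",
                      "<interactorRef>zz9</interactorRef>",
                      paste(lines, collapse = "\n")),
      function() c(lines, "<broken")))(),
    drugbank = sub("(?s)<drugbank-id>.*?</drugbank-id>", "",
                   paste(lines, collapse = "\n"), perl = TRUE),
    kegg_pathway = lines[!startsWith(lines, "ENTRY")],
    kegg_enzyme = lines[!startsWith(lines, "ENTRY")],
    obo = sub("(?s)<id>.*?</id>", "", paste(lines, collapse = "\n"), perl = TRUE)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
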