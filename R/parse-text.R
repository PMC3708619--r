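# Strict parsers for the delimited-text source dialects.
#
# Each parser consumes a documented SUBSET of the real public format:
# unknown trailing columns are ignored, but any malformed consumed field is
# fatal (condition class "wh_parse_error" with a line locator), so a
# transactional load can guarantee the store is untouched on bad input.

#' Parse an NCBI taxonomy dump (nodes + names)
#'
#' Dialect: rows are `"\t|\t"`-delimited and `"\t|"`-terminated.  The nodes
#' stream carries `tax_id | parent tax_id | rank` (further columns of the
#' full taxdump are ignored); the names stream carries
#' `tax_id | name | unique name | name class`.  The class
#' `"scientific name"` provides `scientific_name`; every other class row is
#' attached as a synonym in file order.  A names row for an unknown tax_id,
#' a non-integer tax_id, or a short row is fatal.
#'
#' @param nodes_src,names_src File path or literal text.
#' @return A `taxonomy` record data.frame.
#' @export
parse_taxonomy_dump <- function(nodes_src, names_src) {
  split_dmp <- function(line) {
    line <- sub("\t\\|$", "", line)
    strsplit(line, "\t|\t", fixed = TRUE)[[1]]
  }
  nodes_lines <- read_source_lines(nodes_src)
  nodes_lines <- nodes_lines[nzchar(nodes_lines)]
  n_read <- 0L
  tax_id <- parent <- integer(length(nodes_lines))
  rank <- character(length(nodes_lines))
  for (i in seq_along(nodes_lines)) {
    f <- split_dmp(nodes_lines[i])
    if (length(f) < 3)
      wh_parse_stop(sprintf("nodes line %d: expected 3 fields, got %d", i, length(f)),
                    locator = sprintf("nodes:%d", i), records_read = n_read)
    if (!grepl("^[0-9]+$", f[1]) || !grepl("^[0-9]+$", f[2]))
      wh_parse_stop(sprintf("nodes line %d: non-integer tax_id", i),
                    locator = sprintf("nodes:%d", i), records_read = n_read)
    tax_id[i] <- as.integer(f[1]); parent[i] <- as.integer(f[2]); rank[i] <- f[3]
    n_read <- n_read + 1L
  }
  sci <- stats::setNames(rep(NA_character_, length(tax_id)), tax_id)
  syn <- stats::setNames(empty_chr_list(length(tax_id)), tax_id)
  names_lines <- read_source_lines(names_src)
  names_lines <- names_lines[nzchar(names_lines)]
  for (i in seq_along(names_lines)) {
    f <- split_dmp(names_lines[i])
    if (length(f) < 4)
      wh_parse_stop(sprintf("names line %d: expected 4 fields, got %d", i, length(f)),
                    locator = sprintf("names:%d", i), records_read = n_read)
    if (!grepl("^[0-9]+$", f[1]))
      wh_parse_stop(sprintf("names line %d: non-integer tax_id", i),
                    locator = sprintf("names:%d", i), records_read = n_read)
    id <- f[1]
    if (!id %in% names(sci))
      wh_parse_stop(sprintf("names line %d: name for unknown tax_id %s", i, id),
                    locator = sprintf("names:%d", i), records_read = n_read)
    if (identical(f[4], "scientific name")) sci[[id]] <- f[2]
    else syn[[id]] <- c(syn[[id]], f[2])
  }
  wh_record_frame("taxonomy",
    tax_id = tax_id, parent_tax_id = parent, rank = rank,
    scientific_name = unname(sci[as.character(tax_id)]),
    synonyms = unname(syn[as.character(tax_id)]))
}

#' Parse an NCBI gene_info table
#'
#' Dialect: tab-delimited with a leading `#` header line; the first five
#' columns are `tax_id GeneID Symbol LocusTag Synonyms`, synonyms
#' `|`-separated with `-` meaning none.  Non-numeric GeneID or tax_id is
#' fatal.
#'
#' @param src File path or literal text.
#' @return A `gene` record data.frame.
#' @export
parse_gene_info <- function(src) {
  lines <- read_source_lines(src)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) return(wh_empty_records("gene"))
  gene_id <- tax_id <- integer(length(body))
  symbol <- locus <- character(length(body))
  synonyms <- empty_chr_list(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5)
      wh_parse_stop(sprintf("gene_info line %d: expected >=5 columns, got %d", i, length(f)),
                    locator = sprintf("line:%d", i), records_read = i - 1L)
    if (!grepl("^[0-9]+$", f[2]) || !grepl("^[0-9]+$", f[1]))
      wh_parse_stop(sprintf("gene_info line %d: non-numeric GeneID or tax_id", i),
                    locator = sprintf("line:%d", i), records_read = i - 1L)
    tax_id[i] <- as.integer(f[1]); gene_id[i] <- as.integer(f[2])
    symbol[i] <- f[3]; locus[i] <- f[4]
    if (!identical(f[5], "-") && nzchar(f[5]))
      synonyms[[i]] <- strsplit(f[5], "|", fixed = TRUE)[[1]]
  }
  wh_record_frame("gene", gene_id = gene_id, locus_tag = locus,
                  symbol = symbol, tax_id = tax_id, synonyms = synonyms)
}

#' Parse an NCBI PTT gene-coordinate table
#'
#' Dialect: two header lines (the first word of line 1 is taken as the
#' replicon accession), a column-header line, then tab-delimited rows of
#' `Location Strand Length PID Gene Synonym Code COG Product` with
#' `start..end` locations, 1-based inclusive.  In this dialect the PID
#' column carries the protein accession that links the entry to a protein
#' record.  A malformed location or `start > end` is fatal.
#'
#' @param src File path or literal text.
#' @return A `ptt` record data.frame, rows in file order.
#' @export
parse_ptt <- function(src) {
  lines <- read_source_lines(src)
  if (length(lines) < 3) {
    if (all(!nzchar(lines))) return(wh_empty_records("ptt"))
    wh_parse_stop("PTT file shorter than its 3 header lines", locator = "header")
  }
  replicon <- strsplit(trimws(lines[1]), "[ \t]+")[[1]][1]
  if (is.na(replicon) || !nzchar(replicon))
    wh_parse_stop("PTT header line 1 must start with the replicon accession",
                  locator = "header")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- wh_empty_records("ptt")
    return(out)
  }
  start <- end <- integer(length(body))
  strand <- pid <- gene <- locus <- product <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      wh_parse_stop(sprintf("PTT line %d: expected 9 columns, got %d", i + 3L, length(f)),
                    locator = sprintf("line:%d", i + 3L), records_read = i - 1L)
    loc <- f[1]
    if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc))
      wh_parse_stop(sprintf("PTT line %d: malformed location '%s'", i + 3L, loc),
                    locator = sprintf("line:%d", i + 3L), records_read = i - 1L)
    se <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    if (se[1] > se[2])
      wh_parse_stop(sprintf("PTT line %d: start %d > end %d", i + 3L, se[1], se[2]),
                    locator = sprintf("line:%d", i + 3L), records_read = i - 1L)
    start[i] <- se[1]; end[i] <- se[2]
    strand[i] <- f[2]; pid[i] <- f[4]; gene[i] <- f[5]; locus[i] <- f[6]
    product[i] <- f[9]
  }
  wh_record_frame("ptt",
    replicon_accession = rep(replicon, length(body)),
    start_bp = start, end_bp = end, strand = strand, pid = pid,
    gene_symbol = gene, locus_tag = locus, product = product)
}

# --- KEGG flat files -------------------------------------------------------

# Split a KEGG flat file into blocks of (keyword, value) pairs.  The keyword
# field is fixed at 12 columns; continuation lines start with 12 spaces.
# "///" terminates a block and is optional before EOF.
kegg_blocks <- function(lines) {
  blocks <- list()
  cur <- list()
  last_kw <- NULL
  flush <- function() {
    if (length(cur) > 0) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- list(); last_kw <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "///")) { flush(); next }
    kw <- trimws(substr(line, 1, 12))
    val <- trimws(substring(line, 13))
    if (nzchar(kw)) {
      last_kw <- kw
      cur[[length(cur) + 1L]] <- list(kw = kw, val = val, line = i)
    } else {
      if (is.null(last_kw))
        wh_parse_stop(sprintf("KEGG line %d: continuation before any keyword", i),
                      locator = sprintf("line:%d", i))
      cur[[length(cur) + 1L]] <- list(kw = last_kw, val = val, line = i)
    }
  }
  flush()
  blocks
}

kegg_field <- function(block, kw) {
  vals <- vapply(block, function(x) if (identical(x$kw, kw)) x$val else NA_character_,
                 character(1))
  vals[!is.na(vals)]
}

#' Parse KEGG flat files (pathway or enzyme dialect)
#'
#' Dialect: 12-column keyword field (`ENTRY`, `NAME`, `ORGANISM`, `MEMBER` /
#' `PROTEIN`), continuation lines indented 12 spaces, blocks terminated by
#' `///` (optional before EOF).  Pathway blocks carry the org-prefixed KEGG
#' id in `ENTRY`, the organism tax id as `[TAX:n]` on the `ORGANISM` line,
#' and one member protein accession per `MEMBER` line.  Enzyme blocks carry
#' `ENTRY       EC n.n.n.n`, one name per `NAME` line and accessions on
#' `PROTEIN` lines.  A block without `ENTRY` is fatal.
#'
#' @param src File path or literal text.
#' @param kind `"pathway"` or `"enzyme"`.
#' @return A `pathway` or `enzyme` record data.frame.
#' @export
parse_kegg_flat <- function(src, kind = c("pathway", "enzyme")) {
  kind <- match.arg(kind)
  blocks <- kegg_blocks(read_source_lines(src))
  if (length(blocks) == 0)
    return(wh_empty_records(if (kind == "pathway") "pathway" else "enzyme"))
  if (kind == "pathway") {
    recs <- lapply(seq_along(blocks), function(bi) {
      b <- blocks[[bi]]
      entry <- kegg_field(b, "ENTRY")
      if (length(entry) == 0)
        wh_parse_stop(sprintf("KEGG pathway block %d lacks ENTRY", bi),
                      locator = sprintf("block:%d", bi), records_read = bi - 1L)
      kegg_id <- strsplit(trimws(entry[1]), "[ \t]+")[[1]][1]
      org <- kegg_field(b, "ORGANISM")
      tax <- NA_integer_
      if (length(org) > 0) {
        m <- regmatches(org[1], regexpr("\\[TAX:[0-9]+\\]", org[1]))
        if (length(m) == 0)
          wh_parse_stop(sprintf("KEGG pathway block %d: ORGANISM lacks [TAX:n]", bi),
                        locator = sprintf("block:%d", bi), records_read = bi - 1L)
        tax <- as.integer(gsub("[^0-9]", "", m))
      }
      list(kegg_id = kegg_id,
           name = paste(kegg_field(b, "NAME"), collapse = " ") %||% "",
           organism_tax_id = tax,
           member_accessions = kegg_field(b, "MEMBER"),
           map_number = sub("^.*?([0-9]+)$", "\\1", kegg_id))
    })
    wh_record_frame("pathway",
      kegg_id = vapply(recs, `[[`, "", "kegg_id"),
      name = vapply(recs, `[[`, "", "name"),
      organism_tax_id = vapply(recs, `[[`, 1L, "organism_tax_id"),
      member_accessions = lapply(recs, `[[`, "member_accessions"),
      map_number = vapply(recs, `[[`, "", "map_number"))
  } else {
    recs <- lapply(seq_along(blocks), function(bi) {
      b <- blocks[[bi]]
      entry <- kegg_field(b, "ENTRY")
      if (length(entry) == 0)
        wh_parse_stop(sprintf("KEGG enzyme block %d lacks ENTRY", bi),
                      locator = sprintf("block:%d", bi), records_read = bi - 1L)
      ec <- sub("^EC[ \t]+", "", trimws(entry[1]))
      ec <- strsplit(ec, "[ \t]+")[[1]][1]
      list(ec_number = ec, names = kegg_field(b, "NAME"),
           protein_accessions = kegg_field(b, "PROTEIN"))
    })
    wh_record_frame("enzyme",
      ec_number = vapply(recs, `[[`, "", "ec_number"),
      names = lapply(recs, `[[`, "names"),
      protein_accessions = lapply(recs, `[[`, "protein_accessions"))
  }
}
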