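# Entity record sets.
#
# Each entity kind is represented in R as a plain data.frame with one row per
# record; multi-valued fields (synonyms, accessions, cluster members, ...)
# are list-columns of character vectors.  The same frames appear in fixture
# specs, parser output and query results, so the whole pipeline moves a
# single tabular currency around.

.wh_kind_columns <- list(
  taxonomy    = c("tax_id", "parent_tax_id", "rank", "scientific_name", "synonyms"),
  gene        = c("gene_id", "locus_tag", "symbol", "tax_id", "synonyms"),
  ptt         = c("replicon_accession", "start_bp", "end_bp", "strand", "pid",
                  "gene_symbol", "locus_tag", "product"),
  protein     = c("primary_accession", "accessions", "name", "sequence",
                  "tax_id", "gene_locus_tags"),
  interaction = c("source_dataset", "interactor_a", "interactor_b",
                  "detection_method", "pubmed_id"),
  uniref      = c("cluster_id", "representative_accession", "member_accessions"),
  drug        = c("drugbank_id", "name", "description", "target_accessions"),
  pathway     = c("kegg_id", "name", "organism_tax_id", "member_accessions",
                  "map_number"),
  enzyme      = c("ec_number", "names", "protein_accessions"),
  term        = c("term_id", "name", "namespace", "is_a_parents")
)

.wh_list_columns <- list(
  taxonomy = "synonyms", gene = "synonyms", ptt = character(0),
  protein = c("accessions", "gene_locus_tags"), interaction = character(0),
  uniref = "member_accessions", drug = "target_accessions",
  pathway = "member_accessions", enzyme = c("names", "protein_accessions"),
  term = "is_a_parents"
)

.wh_int_columns <- list(
  taxonomy = c("tax_id", "parent_tax_id"), gene = c("gene_id", "tax_id"),
  ptt = c("start_bp", "end_bp"), protein = "tax_id",
  interaction = character(0), uniref = character(0), drug = character(0),
  pathway = "organism_tax_id", enzyme = character(0), term = character(0)
)

wh_kinds <- function() names(.wh_kind_columns)

#' Construct a validated record set
#'
#' Coerces a data.frame to the canonical column layout of an entity kind and
#' checks the per-record invariants (coordinate ordering, accession layout,
#' amino-acid alphabet, ...).  Cross-record uniqueness is enforced again at
#' insert time against the store.
#'
#' @param kind One of `wh_kinds()`.
#' @param data A data.frame carrying the kind's columns; multi-valued fields
#'   as list-columns of character vectors.
#' @return The normalized data.frame with a `wh_kind` attribute.
#' @export
wh_records <- function(kind, data) {
  kind <- match.arg(kind, wh_kinds())
  cols <- .wh_kind_columns[[kind]]
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    wh_constraint_stop(sprintf("%s records lack column(s): %s",
                               kind, paste(missing_cols, collapse = ", ")))
  }
  data <- as.data.frame(data)[, cols, drop = FALSE]
  rownames(data) <- NULL
  for (col in .wh_int_columns[[kind]]) data[[col]] <- as.integer(data[[col]])
  for (col in .wh_list_columns[[kind]]) {
    data[[col]] <- lapply(data[[col]], function(x) as.character(x %||% character(0)))
  }
  for (col in setdiff(cols, c(.wh_int_columns[[kind]], .wh_list_columns[[kind]]))) {
    data[[col]] <- as.character(data[[col]])
  }
  wh_validate_rows(kind, data)
  attr(data, "wh_kind") <- kind
  data
}

# Per-row (within-batch) invariant checks.  Raise wh_constraint_error.
wh_validate_rows <- function(kind, data) {
  n <- nrow(data)
  if (n == 0) return(invisible(TRUE))
  fail <- function(msg) wh_constraint_stop(sprintf("invalid %s record: %s", kind, msg))
  dup <- function(x) x[duplicated(x)]
  switch(kind,
    taxonomy = {
      if (anyNA(data$tax_id) || any(data$tax_id <= 0)) fail("tax_id must be a positive integer")
      if (anyDuplicated(data$tax_id)) fail(sprintf("duplicate tax_id %s", dup(data$tax_id)[1]))
    },
    gene = {
      if (anyNA(data$gene_id) || any(data$gene_id <= 0)) fail("gene_id must be a positive integer")
      if (anyDuplicated(data$gene_id)) fail(sprintf("duplicate gene_id %s", dup(data$gene_id)[1]))
      key <- paste(data$tax_id, toupper(data$locus_tag))
      key <- key[!is.na(data$locus_tag) & nzchar(data$locus_tag)]
      if (anyDuplicated(key)) fail(sprintf("duplicate locus_tag within tax_id: %s", dup(key)[1]))
    },
    ptt = {
      if (anyNA(data$start_bp) || anyNA(data$end_bp)) fail("missing coordinates")
      if (any(data$start_bp > data$end_bp)) fail("start_bp > end_bp")
      if (any(data$start_bp < 1)) fail("coordinates are 1-based")
      if (!all(data$strand %in% c("+", "-"))) fail("strand must be + or -")
      key <- paste(toupper(data$replicon_accession), toupper(data$locus_tag))
      if (anyDuplicated(key)) fail(sprintf("duplicate (replicon, locus_tag): %s", dup(key)[1]))
    },
    protein = {
      if (any(lengths(data$accessions) == 0)) fail("protein without accession")
      first <- vapply(data$accessions, `[`, character(1), 1)
      if (!identical(toupper(first), toupper(data$primary_accession)))
        fail("primary_accession must be the first accession")
      acc <- toupper(unlist(data$accessions))
      if (anyDuplicated(acc)) fail(sprintf("accession on two proteins: %s", dup(acc)[1]))
      if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWYBXZJUO]*$", data$sequence)))
        fail("sequence must use the uppercase one-letter amino-acid alphabet")
    },
    interaction = {
      if (any(!nzchar(data$source_dataset) | is.na(data$source_dataset)))
        fail("source_dataset must be non-empty")
      if (any(!nzchar(data$interactor_a) | !nzchar(data$interactor_b)))
        fail("interactors must be non-empty")
    },
    uniref = {
      if (anyDuplicated(toupper(data$cluster_id))) fail("duplicate cluster_id")
      ok <- mapply(function(rep, mem) toupper(rep) %in% toupper(mem),
                   data$representative_accession, data$member_accessions)
      if (!all(ok)) fail("representative must be among the members")
      mem <- toupper(unlist(data$member_accessions))
      if (anyDuplicated(mem)) fail(sprintf("accession in two clusters: %s", dup(mem)[1]))
    },
    drug = {
      if (any(!grepl("^DB[0-9A-Za-z]+$", data$drugbank_id))) fail("malformed drugbank_id")
      if (anyDuplicated(toupper(data$drugbank_id))) fail("duplicate drugbank_id")
    },
    pathway = {
      if (any(!nzchar(data$kegg_id))) fail("missing kegg_id")
      if (anyDuplicated(toupper(data$kegg_id))) fail("duplicate kegg_id")
      tail5 <- sub("^.*?([0-9]+)$", "\\1", data$kegg_id)
      if (!identical(tail5, data$map_number)) fail("map_number must be the trailing digits of kegg_id")
    },
    enzyme = {
      if (any(!grepl("^[0-9]+(\\.[0-9n-]+){1,3}$", data$ec_number))) fail("malformed ec_number")
      if (anyDuplicated(data$ec_number)) fail("duplicate ec_number")
    },
    term = {
      if (any(!nzchar(data$term_id))) fail("missing term_id")
      if (anyDuplicated(toupper(data$term_id))) fail("duplicate term_id")
    }
  )
  invisible(TRUE)
}

# An empty record frame of a given kind (used by parsers and fixtures).
wh_empty_records <- function(kind) {
  cols <- .wh_kind_columns[[kind]]
  out <- data.frame()
  for (col in cols) {
    out[[col]] <- if (col %in% .wh_list_columns[[kind]]) list()
                  else if (col %in% .wh_int_columns[[kind]]) integer(0)
                  else character(0)
  }
  attr(out, "wh_kind") <- kind
  out
}

# Assemble a record frame from parallel vectors/lists, tolerating zero rows.
wh_record_frame <- function(kind, ...) {
  vals <- list(...)
  cols <- .wh_kind_columns[[kind]]
  stopifnot(identical(sort(names(vals)), sort(cols)))
  n <- max(c(0L, vapply(vals[setdiff(cols, .wh_list_columns[[kind]])], length, 1L)))
  if (n == 0 && all(lengths(vals) == 0)) return(wh_empty_records(kind))
  out <- data.frame(row.names = seq_len(n))
  for (col in cols) {
    out[[col]] <- if (col %in% .wh_list_columns[[kind]]) {
      v <- vals[[col]]
      if (length(v) == 0) empty_chr_list(n) else v
    } else vals[[col]]
  }
  wh_records(kind, out)
}
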