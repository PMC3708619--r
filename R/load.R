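# Transactional loading of source files into a store.

.wh_formats <- c("taxdump", "gene_info", "ptt", "uniprot", "uniref",
                 "psimi", "drugbank", "kegg_pathway", "kegg_enzyme", "obo")

wh_format_kind <- c(
  taxdump = "taxonomy", gene_info = "gene", ptt = "ptt", uniprot = "protein",
  uniref = "uniref", psimi = "interaction", drugbank = "drug",
  kegg_pathway = "pathway", kegg_enzyme = "enzyme", obo = "term")

#' Supported source format tags
#' @return Character vector of format tags accepted by [wh_load()].
#' @export
wh_formats <- function() .wh_formats

parse_report <- function(records_read, records_loaded, failure = NULL) {
  structure(list(records_read = as.integer(records_read),
                 records_loaded = as.integer(records_loaded),
                 failure = failure),
            class = "parse_report")
}

#' @export
print.parse_report <- function(x, ...) {
  cat("<parse report> read:", x$records_read, " loaded:", x$records_loaded, "\n")
  if (!is.null(x$failure))
    cat("  FAILED at ", x$failure$locator %||% "?", ": ", x$failure$message,
        "\n", sep = "")
  invisible(x)
}

#' Load a source file into the store
#'
#' Parses a source file in one of the supported dialects and inserts all of
#' its records in a single transaction.  The loader is strict: on any parse
#' error or invariant violation nothing is inserted and the store file is
#' left exactly as it was (parsing and validation complete before a write
#' transaction is opened, and an insert-stage failure rolls back).
#'
#' @param store A `wh_store`.
#' @param path Source path; for `format = "taxdump"` either a directory
#'   containing `nodes.dmp` and `names.dmp` or a length-2 vector
#'   `c(nodes, names)`.
#' @param format One of [wh_formats()].
#' @return A `parse_report` with `records_read`, `records_loaded` and, on
#'   failure, a locator + message; `failure` non-NULL implies
#'   `records_loaded == 0`.
#' @export
wh_load <- function(store, path, format) {
  format <- match.arg(format, .wh_formats)
  result <- tryCatch({
    records <- switch(format,
      taxdump = {
        if (length(path) == 1 && dir.exists(path))
          path <- file.path(path, c("nodes.dmp", "names.dmp"))
        if (length(path) != 2)
          wh_parse_stop("taxdump needs a nodes and a names source", locator = "input")
        missing_f <- path[!file.exists(path)]
        if (length(missing_f))
          wh_parse_stop(paste("missing file:", missing_f[1]), locator = "input")
        parse_taxonomy_dump(path[1], path[2])
      },
      {
        if (!file.exists(path))
          wh_parse_stop(paste("missing file:", path), locator = "input")
        switch(format,
          gene_info = parse_gene_info(path),
          ptt = parse_ptt(path),
          uniprot = parse_uniprot_xml(path),
          uniref = parse_uniref_xml(path),
          psimi = parse_psimi25(path),
          drugbank = parse_drugbank_xml(path),
          kegg_pathway = parse_kegg_flat(path, "pathway"),
          kegg_enzyme = parse_kegg_flat(path, "enzyme"),
          obo = parse_obo_xml(path))
      })
    n <- nrow(records)
    tryCatch({
      wh_insert(store, wh_format_kind[[format]], records)
      parse_report(n, n)
    },
    wh_constraint_error = function(e) {
      parse_report(n, 0L,
                   failure = list(locator = "validation",
                                  message = conditionMessage(e)))
    })
  },
  wh_parse_error = function(e) {
    parse_report(e$records_read %||% 0L, 0L,
                 failure = list(locator = e$locator %||% "?",
                                message = conditionMessage(e)))
  },
  wh_constraint_error = function(e) {
    # invariant violation detected while assembling parsed records
    parse_report(0L, 0L,
                 failure = list(locator = "validation",
                                message = conditionMessage(e)))
  })
  if (is.null(result$failure))
    message(sprintf("loaded %d %s record(s) from %s", result$records_loaded,
                    format, paste(path, collapse = ", ")))
  else
    message(sprintf("load of %s FAILED at %s: %s; store unchanged",
                    paste(path, collapse = ", "),
                    result$failure$locator, result$failure$message))
  result
}
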