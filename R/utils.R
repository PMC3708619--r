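`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

#' @keywords internal
wh_parse_stop <- function(message, locator = NULL, records_read = 0L) {
  cond <- structure(
    class = c("wh_parse_error", "error", "condition"),
    list(message = message, call = sys.call(-1),
         locator = locator, records_read = as.integer(records_read))
  )
  stop(cond)
}

#' @keywords internal
wh_constraint_stop <- function(message) {
  cond <- structure(
    class = c("wh_constraint_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

#' @keywords internal
wh_usage_stop <- function(message) {
  cond <- structure(
    class = c("wh_usage_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  )
  stop(cond)
}

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Read a text source given either a path or literal text (possibly with
# embedded newlines).  Returns a character vector of lines.
read_source_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1 && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE, encoding = "UTF-8"))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# Random amino-acid sequence (uppercase one-letter alphabet).
random_aa_seq <- function(n = 30L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

empty_chr_list <- function(n) replicate(n, character(0), simplify = FALSE)
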