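#' Internal condition helpers
#'
#' All package errors carry the class `kce_error` plus a specific subclass so
#' callers (and tests) can distinguish validation failures from, e.g., a
#' missing embedding token.
#' @noRd
kce_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "kce_error", "error", "condition")))
}

#' Encode (pk, cancer) pairs as a single key string
#'
#' Pairs are passed around as two-column tables; set operations (disjointness,
#' sampling, exclusion) work on these keys. The separator is a control
#' character that cannot occur in kinase symbols or MeSH ids.
#' @noRd
pair_key <- function(pk, cancer) paste(pk, cancer, sep = "\x1f")

#' Decode pair keys back into a two-column data.table
#' @noRd
pair_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(data.table(pk = character(), cancer = character()))
  }
  parts <- strsplit(keys, "\x1f", fixed = TRUE)
  data.table(
    pk     = vapply(parts, `[`, character(1), 1L),
    cancer = vapply(parts, `[`, character(1), 2L)
  )
}

#' Validate a scalar positive integer-ish argument
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    kce_stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                     name, min, deparse(x)), "kce_config_error")
  }
  as.integer(x)
}

#' Open a possibly gzip-compressed text connection for reading
#' @noRd
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt", encoding = "UTF-8")
  else file(path, "rt", encoding = "UTF-8")
}
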