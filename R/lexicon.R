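#' English stop-word list used by the text preprocessor
#'
#' The standard English stop-word list shipped with the package, extended with
#' all 52 single-letter tokens (both cases are covered because single-character
#' tokens are removed unconditionally and capitalized forms of stop words are
#' matched explicitly). The list ships as a versioned plain-text data file so
#' tokenization results are stable across installations.
#'
#' @return Character vector of lowercase stop words.
#' @export
#' @examples
#' head(kce_stopwords())
kce_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "kce", mustWork = TRUE)
  unique(readLines(path, encoding = "UTF-8"))
}

#' Dictionary lemmatizer
#'
#' Reduces inflected English word forms to dictionary base forms: regular
#' plural nouns by suffix rules (`kinases` -> `kinase`, `studies` -> `study`,
#' `classes` -> `class`) and irregular plurals plus comparative/superlative
#' adjectives (`higher` -> `high`, `children` -> `child`) through a shipped
#' exception dictionary. Unlike a stemmer the result is always a complete
#' word: forms the rules do not cover are returned unchanged. Tokens
#' containing digits (concept tokens such as `meshd002289`) are never touched.
#'
#' @param tokens Character vector of lowercase-or-mixed-case tokens.
#' @return Character vector of the same length with base forms substituted.
#' @export
#' @examples
#' kce_lemmatize(c("kinases", "studies", "higher", "mice", "cancer"))
kce_lemmatize <- function(tokens) {
  if (length(tokens) == 0L) return(character())
  dict <- lemma_dict()
  out <- tokens
  low <- tolower(tokens)
  hit <- match(low, names(dict))
  out[!is.na(hit)] <- dict[hit[!is.na(hit)]]
  todo <- is.na(hit) & !grepl("[0-9]", tokens) & nchar(tokens) >= 4L
  out[todo] <- vapply(tolower(tokens[todo]), lemma_rules, character(1), USE.NAMES = FALSE)
  out
}

# suffix rules for regular plural nouns; conservative so that words like
# "cancer", "analysis", "virus" pass through unchanged
lemma_rules <- function(w) {
  n <- nchar(w)
  if (endsWith(w, "ies") && n >= 5L) {
    return(paste0(substr(w, 1L, n - 3L), "y"))
  }
  if (endsWith(w, "sses") || endsWith(w, "ches") || endsWith(w, "shes") ||
      endsWith(w, "xes") || endsWith(w, "zes")) {
    return(substr(w, 1L, n - 2L))
  }
  if (endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us") &&
      !endsWith(w, "is")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

lemma_dict <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "lemma_exceptions.tsv", package = "kce",
                          mustWork = TRUE)
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      cache <<- stats::setNames(tab$base, tab$inflected)
    }
    cache
  }
})
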