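#' Parse an article table into article records
#'
#' Reads one of the two supported dialects of article metadata and returns a
#' normalized record table. The TSV dialect has a header row and six columns:
#' `pmid`, `year` (one year or several joined by `;`; the earliest is kept),
#' `mesh_ids` (`;`-joined MeSH descriptor ids), `keywords` (`;`-joined),
#' `title`, `abstract`. Files ending in `.gz` are read transparently. The XML
#' dialect is a simplified PubMed-style stream:
#'
#' ```
#' <ArticleSet>
#'   <Article>
#'     <PMID>123</PMID>
#'     <Date Year="2001"/> <Date Year="1999"/>
#'     <MeshHeading>D009369</MeshHeading>
#'     <Keyword>neoplasms</Keyword>
#'     <Title>...</Title>
#'     <Abstract>...</Abstract>
#'   </Article>
#' </ArticleSet>
#' ```
#'
#' A record's `year` is the minimum over all dated fields of the source
#' record. A missing abstract yields an empty `abstract` string, not an error.
#'
#' @param source Path to a `.tsv`/`.tsv.gz` or `.xml` file.
#' @param format One of `"auto"` (by file extension), `"tsv"`, `"xml"`.
#' @return A `data.table` with columns `pmid` (character), `year` (integer),
#'   `mesh_ids` (list of character), `keywords` (list of character), `title`,
#'   `abstract` (character).
#' @export
parse_articles <- function(source, format = c("auto", "tsv", "xml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xml(\\.gz)?$", source)) "xml" else "tsv"
  }
  if (format == "xml") parse_articles_xml(source) else parse_articles_tsv(source)
}

parse_articles_tsv <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               quote = "", na.strings = NULL, encoding = "UTF-8")
  need <- c("pmid", "year", "mesh_ids", "keywords", "title", "abstract")
  if (!all(need %in% names(tab))) {
    kce_stop(sprintf("article table is missing column(s): %s",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "kce_parse_error")
  }
  if (nrow(tab) == 0L) return(empty_articles())
  years <- vapply(seq_len(nrow(tab)), function(i) {
    parse_year_field(tab$year[i], tab$pmid[i], i)
  }, integer(1))
  if (anyNA(tab$pmid) || any(tab$pmid == "")) {
    kce_stop(sprintf("article table row %d: empty field `pmid`",
                     which(tab$pmid == "" | is.na(tab$pmid))[1L]),
             "kce_parse_error")
  }
  data.table(
    pmid     = tab$pmid,
    year     = years,
    mesh_ids = split_semicolon(tab$mesh_ids),
    keywords = split_semicolon(tab$keywords),
    title    = tab$title,
    abstract = tab$abstract
  )
}

parse_articles_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//Article")
  if (length(arts) == 0L) return(empty_articles())
  recs <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, "./PMID"))
    if (is.na(pmid) || pmid == "") {
      kce_stop("XML article element without a <PMID>", "kce_parse_error")
    }
    yrs <- xml2::xml_attr(xml2::xml_find_all(a, "./Date"), "Year")
    yr <- suppressWarnings(as.integer(yrs))
    if (length(yr) == 0L || anyNA(yr)) {
      kce_stop(sprintf("article %s: missing or unparseable field `year`", pmid),
               "kce_parse_error")
    }
    abst <- xml2::xml_text(xml2::xml_find_first(a, "./Abstract"))
    list(
      pmid     = pmid,
      year     = min(yr),
      mesh_ids = list(xml2::xml_text(xml2::xml_find_all(a, "./MeshHeading"))),
      keywords = list(xml2::xml_text(xml2::xml_find_all(a, "./Keyword"))),
      title    = xml2::xml_text(xml2::xml_find_first(a, "./Title")),
      abstract = if (is.na(abst)) "" else abst
    )
  })
  rbindlist(recs)
}

empty_articles <- function() {
  data.table(pmid = character(), year = integer(), mesh_ids = list(),
             keywords = list(), title = character(), abstract = character())
}

parse_year_field <- function(x, pmid, row) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  yr <- suppressWarnings(as.integer(parts))
  if (length(yr) == 0L || anyNA(yr)) {
    kce_stop(sprintf("article %s (row %d): unparseable field `year`: %s",
                     pmid, row, deparse(x)), "kce_parse_error")
  }
  min(yr)
}

split_semicolon <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(p) p[nzchar(p)])
}

#' Read a MeSH hierarchy from JSON-lines
#'
#' One descriptor per line, as a JSON object with fields `id`, `label`,
#' `synonyms` (array, may be empty) and `parents` (array of descriptor ids,
#' empty for roots).
#'
#' @param path Path to the JSON-lines file (optionally `.gz`).
#' @return An object of class `kce_mesh`: a named list of nodes, each a list
#'   with `label`, `synonyms` and `parents`.
#' @export
read_mesh_hierarchy <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  nodes <- list()
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    if (is.null(rec$id) || is.null(rec$label)) {
      kce_stop(sprintf("MeSH hierarchy line %d: missing `id` or `label`", i),
               "kce_parse_error")
    }
    nodes[[rec$id]] <- list(
      label    = rec$label,
      synonyms = as.character(rec$synonyms %||% character()),
      parents  = as.character(rec$parents %||% character())
    )
  }
  structure(nodes, class = "kce_mesh")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Descendant closure of a set of MeSH descriptors
#'
#' Returns the given descriptors plus every descriptor reachable from them by
#' following child links (i.e. all subcategories), using the parent pointers
#' stored in the hierarchy.
#'
#' @param hierarchy A `kce_mesh` object from [read_mesh_hierarchy()].
#' @param ids Character vector of descriptor ids; must all be hierarchy nodes.
#' @return Character vector of descriptor ids, a superset of `ids`.
#' @export
mesh_closure <- function(hierarchy, ids) {
  stopifnot(inherits(hierarchy, "kce_mesh"))
  unknown <- setdiff(ids, names(hierarchy))
  if (length(unknown) > 0L) {
    kce_stop(sprintf("descriptor id(s) not in hierarchy: %s",
                     paste(unknown, collapse = ", ")), "kce_config_error")
  }
  # invert parent pointers once
  parents <- lapply(hierarchy, `[[`, "parents")
  child_of <- split(
    rep(names(hierarchy), lengths(parents)),
    unlist(parents, use.names = FALSE)
  )
  seen <- character()
  queue <- unique(ids)
  while (length(queue) > 0L) {
    seen <- c(seen, queue)
    kids <- unique(unlist(child_of[queue], use.names = FALSE))
    queue <- setdiff(kids, seen)
  }
  unique(seen)
}

#' Select articles relevant to a MeSH descriptor search
#'
#' An article is relevant if it has a non-empty abstract and either carries at
#' least one MeSH descriptor in the descendant closure of the search set, or
#' has a keyword that case-insensitively equals a label or synonym of a
#' closure descriptor. Articles with neither descriptors nor keywords cannot
#' match. Input order is preserved; descriptor ids on articles that are not in
#' the hierarchy are ignored.
#'
#' @param articles Article table from [parse_articles()].
#' @param search_ids High-level MeSH descriptor ids defining the search scope
#'   (e.g. `c("D009369", "D011494")` for neoplasms and protein kinases).
#' @param hierarchy A `kce_mesh` object.
#' @return The subset of `articles` judged relevant, original order.
#' @export
select_relevant <- function(articles, search_ids, hierarchy) {
  closure <- mesh_closure(hierarchy, search_ids)
  terms <- unlist(lapply(hierarchy[closure], function(n) c(n$label, n$synonyms)),
                  use.names = FALSE)
  terms <- unique(tolower(terms))
  keep <- vapply(seq_len(nrow(articles)), function(i) {
    if (!nzchar(articles$abstract[i])) return(FALSE)
    if (length(intersect(articles$mesh_ids[[i]], closure)) > 0L) return(TRUE)
    kw <- articles$keywords[[i]]
    length(kw) > 0L && any(tolower(kw) %in% terms)
  }, logical(1))
  articles[keep]
}

#' Read a concept-annotation table (PubTator offset style)
#'
#' Five tab-separated columns with header: `pmid`, `start`, `end` (0-based
#' half-open character offsets into title + single space + abstract),
#' `category` (one of chemical, disease, gene, cellline, snp, species) and
#' `concept_id`.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A `data.table` with the five columns, offsets as integers.
#' @export
read_annotations <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("pmid", "category", "concept_id"),
    integer = c("start", "end")), quote = "", encoding = "UTF-8")
  need <- c("pmid", "start", "end", "category", "concept_id")
  if (!all(need %in% names(tab))) {
    kce_stop(sprintf("annotation table is missing column(s): %s",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "kce_parse_error")
  }
  tab[, need, with = FALSE]
}

#' Build the concept token for an annotation
#'
#' Tokens use a lowercase namespace prefix plus the identifier so that they
#' are collision-free and survive lowercasing: `meshd002289` (diseases and
#' chemicals), `ncbigene1956` (genes), `taxon10090` (species), `cvcl0023`
#' (cell lines), `rs334` (SNPs).
#'
#' @param category Annotation category string.
#' @param concept_id Namespaced or bare identifier as found in the annotation.
#' @return A single lowercase token.
#' @export
concept_token <- function(category, concept_id) {
  id <- tolower(gsub("[^[:alnum:]]", "", sub("^[Mm][Ee][Ss][Hh]:", "", concept_id)))
  switch(tolower(category),
    chemical = ,
    disease  = paste0("mesh", sub("^mesh", "", id)),
    gene     = paste0("ncbigene", sub("^(ncbi)?gene", "", id)),
    species  = paste0("taxon", sub("^taxon", "", id)),
    cellline = paste0("cvcl", sub("^cvcl", "", id)),
    snp      = if (startsWith(id, "rs")) id else paste0("rs", id),
    kce_stop(sprintf("unknown annotation category: %s", category),
             "kce_parse_error")
  )
}

#' Replace annotated concept spans in an article's text
#'
#' Operates on the concatenation `title + " " + abstract` (the offset base of
#' the annotation dialect). Each surviving annotated span is replaced by its
#' concept token; text outside annotated spans is preserved byte for byte.
#' Species annotations for human (NCBI taxon 9606) are skipped so that
#' age- and gender-bearing words like *patient* or *woman* stay in the text.
#' Overlapping annotations are resolved by keeping the longest span, ties
#' broken by leftmost start, then lexicographic concept id; replacements are
#' applied in descending start order so earlier offsets stay valid.
#'
#' @param article A single article record (one row of the table from
#'   [parse_articles()], or a list with `pmid`, `title`, `abstract`).
#' @param anns Annotation rows for this article (any order).
#' @return The concept-replaced text, ready for [preprocess_text()].
#' @export
apply_concept_annotations <- function(article, anns) {
  text <- paste(article$title, article$abstract, sep = " ")
  if (is.null(anns) || nrow(anns) == 0L) return(text)
  n <- nchar(text)
  bad <- anns$start < 0L | anns$end > n | anns$start >= anns$end
  if (any(bad)) {
    i <- which(bad)[1L]
    kce_stop(sprintf("article %s: annotation offsets [%d,%d) out of range for text of length %d",
                     article$pmid, anns$start[i], anns$end[i], n),
             "kce_offset_error")
  }
  anns <- as.data.table(anns)
  anns <- anns[!(tolower(category) == "species" &
                   grepl("^(taxon:?)?9606$", tolower(concept_id)))]
  if (nrow(anns) == 0L) return(text)
  # longest span wins; ties by leftmost start, then concept id
  anns[, len := end - start]
  setorderv(anns, c("len", "start", "concept_id"), order = c(-1L, 1L, 1L))
  kept <- logical(nrow(anns))
  covered <- integer(0)
  for (i in seq_len(nrow(anns))) {
    span <- seq.int(anns$start[i] + 1L, anns$end[i])
    if (!any(span %in% covered)) {
      kept[i] <- TRUE
      covered <- c(covered, span)
    }
  }
  anns <- anns[kept]
  setorderv(anns, "start", order = -1L)
  for (i in seq_len(nrow(anns))) {
    tok <- concept_token(anns$category[i], anns$concept_id[i])
    text <- paste0(
      substr(text, 1L, anns$start[i]),
      tok,
      substring(text, anns$end[i] + 1L)
    )
  }
  text
}

#' Normalize concept-replaced text into a token stream
#'
#' Applies, in order: punctuation deletion (including hyphens and underscores;
#' the parts of a compound word become separate tokens), stop-word removal in
#' lowercase and capitalized form with uppercase acronyms of length >= 2
#' retained (`ALL`, the leukemia acronym, survives while `all` and `All` are
#' removed), removal of single-character tokens, dictionary lemmatization
#' ([kce_lemmatize()]), and lowercasing last.
#'
#' @param text Character scalar (concept-replaced title + abstract).
#' @param stopwords Character vector of stop words; default [kce_stopwords()].
#' @return Character vector of lowercase tokens (possibly empty).
#' @export
#' @examples
#' preprocess_text("Untreated ALL progressed; all patients had higher counts.")
preprocess_text <- function(text, stopwords = kce_stopwords()) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(gsub("[^[:alnum:]]+", " ", text), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(character())
  is_acro <- nchar(toks) >= 2L & grepl("^[A-Z][A-Z0-9]*$", toks) &
    grepl("[A-Z]", toks)
  is_cap <- grepl("^[A-Z][a-z]+$", toks)
  drop <- nchar(toks) == 1L |
    (!is_acro & (toks %in% stopwords | (is_cap & tolower(toks) %in% stopwords)))
  toks <- toks[!drop]
  tolower(kce_lemmatize(toks))
}

#' Prepare a token corpus from articles and annotations
#'
#' End-to-end driver for corpus preparation: selects relevant articles,
#' applies concept replacement per article, and tokenizes. Returns one token
#' document per selected article.
#'
#' @inheritParams select_relevant
#' @param annotations Annotation table from [read_annotations()].
#' @param stopwords Stop-word list for [preprocess_text()].
#' @return A `data.table` with columns `pmid`, `year` and `tokens`
#'   (list of character vectors).
#' @export
prep_corpus <- function(articles, annotations, hierarchy, search_ids,
                        stopwords = kce_stopwords()) {
  sel <- select_relevant(articles, search_ids, hierarchy)
  ann_by_pmid <- if (nrow(annotations) > 0L) {
    split(as.data.table(annotations), by = "pmid")
  } else list()
  toks <- lapply(seq_len(nrow(sel)), function(i) {
    txt <- apply_concept_annotations(sel[i], ann_by_pmid[[sel$pmid[i]]])
    preprocess_text(txt, stopwords)
  })
  data.table(pmid = sel$pmid, year = sel$year, tokens = toks)
}

#' Write / read a token corpus
#'
#' One document per line: the pmid, then the space-separated tokens. Written
#' gzip-compressed when the path ends in `.gz`.
#'
#' @param corpus A `data.table` with `pmid` and `tokens` columns.
#' @param path Output (or input) path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns a
#'   corpus `data.table` with `pmid` and `tokens`.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    paste(c(corpus$pmid[i], corpus$tokens[[i]]), collapse = " ")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  data.table(
    pmid   = vapply(parts, `[`, character(1), 1L),
    tokens = lapply(parts, function(p) p[-1L][nzchar(p[-1L])])
  )
}
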