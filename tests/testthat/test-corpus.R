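test_that("TSV article parsing matches a hand-parsed oracle and takes the earliest year", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "pmid\tyear\tmesh_ids\tkeywords\ttitle\tabstract",
    "101\t2001;1999\tD009369;D008175\tlung cancer\tA title\tAn abstract.",
    "102\t2010\t\t\tOnly title\t",
    "103\t1987\tD011494\tkinase;enzyme\tThird\tText here."
  ), tsv)
  arts <- parse_articles(tsv)
  expect_equal(nrow(arts), 3L)
  # hand parse: record 101
  expect_equal(arts$pmid, c("101", "102", "103"))
  expect_equal(arts$year, c(1999L, 2010L, 1987L))  # earliest of 2001;1999
  expect_equal(arts$mesh_ids[[1]], c("D009369", "D008175"))
  expect_equal(arts$keywords[[3]], c("kinase", "enzyme"))
  expect_identical(arts$abstract[2], "")  # missing abstract is empty, not an error
  expect_equal(arts$mesh_ids[[2]], character())
})

test_that("empty article sources give empty record tables", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("pmid\tyear\tmesh_ids\tkeywords\ttitle\tabstract", tsv)
  expect_equal(nrow(parse_articles(tsv)), 0L)
  xml <- tempfile(fileext = ".xml")
  writeLines("<ArticleSet></ArticleSet>", xml)
  expect_equal(nrow(parse_articles(xml)), 0L)
})

test_that("XML article parsing extracts fields and minimum year", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<ArticleSet><Article><PMID>7</PMID>",
    '<Date Year="2001"/><Date Year="1999"/>',
    "<MeshHeading>D008175</MeshHeading><Keyword>NSCLC</Keyword>",
    "<Title>T</Title><Abstract>Alpha beta.</Abstract></Article>",
    "<Article><PMID>8</PMID><Date Year=\"2012\"/><Title>U</Title></Article>",
    "</ArticleSet>"), xml)
  arts <- parse_articles(xml)
  expect_equal(arts$year, c(1999L, 2012L))
  expect_equal(arts$mesh_ids[[1]], "D008175")
  expect_identical(arts$abstract[2], "")
})

test_that("malformed article rows raise errors naming the record and field", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("pmid\tyear\tmesh_ids\tkeywords\ttitle\tabstract",
               "55\tnot_a_year\t\t\tT\tA."), tsv)
  expect_error(parse_articles(tsv), "55.*year", class = "kce_parse_error")
})

test_that("relevance selection uses the descriptor closure, keywords and abstracts", {
  h <- toy_hierarchy()
  arts <- rbind(
    make_article("1", "t", "has abstract", mesh = "D002289"),   # grandchild of D009369
    make_article("2", "t", "", mesh = "D002289"),               # no abstract
    make_article("3", "t", "has abstract", mesh = "D999999"),   # unknown descriptor
    make_article("4", "t", "has abstract", kw = "Lung Cancer"), # keyword = synonym
    make_article("5", "t", "has abstract")                      # nothing to match
  )
  sel <- select_relevant(arts, c("D009369", "D011494"), h)
  expect_equal(sel$pmid, c("1", "4"))
  # monotone: enlarging the search set never removes an article
  sel_small <- select_relevant(arts, "D008175", h)
  expect_true(all(sel_small$pmid %in% sel$pmid))
})

test_that("closure always contains its seed set", {
  h <- toy_hierarchy()
  expect_setequal(mesh_closure(h, "D009369"),
                  c("D009369", "D008175", "D002289"))
  expect_setequal(mesh_closure(h, "D011494"), "D011494")
  expect_error(mesh_closure(h, "D000001"), class = "kce_config_error")
})

test_that("concept replacement substitutes spans and skips human species", {
  art <- make_article("9", "Study of non-small-cell lung carcinoma",
                      "The patient improved.")
  # offsets into "title abstract": the disease phrase and the word "patient"
  anns <- data.table::data.table(
    pmid = "9",
    start = c(9L, 43L), end = c(38L, 50L),
    category = c("disease", "species"),
    concept_id = c("MESH:D002289", "9606"))
  out <- apply_concept_annotations(art, anns)
  expect_identical(out, "Study of meshd002289 The patient improved.")
  # empty annotation set leaves the text untouched
  expect_identical(apply_concept_annotations(art, anns[0]),
                   paste(art$title, art$abstract))
  # non-human species are replaced
  anns2 <- data.table::data.table(pmid = "9", start = 43L, end = 50L,
                                  category = "species", concept_id = "10090")
  expect_match(apply_concept_annotations(art, anns2), "taxon10090")
})

test_that("characters outside annotated spans are preserved", {
  art <- make_article("9", "alpha EGFR beta", "gamma BRAF; delta.")
  anns <- data.table::data.table(pmid = "9", start = c(6L, 22L),
                                 end = c(10L, 26L),
                                 category = "gene", concept_id = c("1956", "673"))
  out <- apply_concept_annotations(art, anns)
  expect_identical(out, "alpha ncbigene1956 beta gamma ncbigene673; delta.")
})

test_that("overlapping annotations keep the longest span, ties leftmost then by id", {
  art <- make_article("9", "abcdefghij", "tail")
  over <- data.table::data.table(
    pmid = "9", start = c(0L, 2L), end = c(6L, 10L),
    category = "gene", concept_id = c("1", "2"))
  # second span is longer (8 > 6): it wins, first is dropped
  expect_identical(apply_concept_annotations(art, over), "abncbigene2 tail")
  tie <- data.table::data.table(
    pmid = "9", start = c(2L, 0L), end = c(6L, 4L),
    category = "gene", concept_id = c("9", "8"))
  # equal lengths: leftmost start wins
  expect_identical(apply_concept_annotations(art, tie), "ncbigene8efghij tail")
})

test_that("out-of-range offsets raise an error naming the article", {
  art <- make_article("77", "short", "text")
  bad <- data.table::data.table(pmid = "77", start = 2L, end = 99L,
                                category = "gene", concept_id = "1")
  expect_error(apply_concept_annotations(art, bad), "77.*99",
               class = "kce_offset_error")
})

test_that("concept tokens are lowercase, namespaced and collision-free", {
  expect_identical(concept_token("disease", "MESH:D002289"), "meshd002289")
  expect_identical(concept_token("chemical", "D008694"), "meshd008694")
  expect_identical(concept_token("gene", "1956"), "ncbigene1956")
  expect_identical(concept_token("species", "10090"), "taxon10090")
  expect_identical(concept_token("cellline", "CVCL_0023"), "cvcl0023")
  expect_identical(concept_token("snp", "rs334"), "rs334")
  expect_error(concept_token("mutation", "x"), class = "kce_parse_error")
})

test_that("preprocessing retains uppercase acronyms but drops stop words either case", {
  toks <- preprocess_text("Untreated ALL progressed but all cases and All controls did not")
  expect_true("all" %in% toks)          # from the acronym ALL, lowercased last
  expect_equal(sum(toks == "all"), 1L)  # 'all' and 'All' were removed pre-lowercasing
  expect_false(any(c("but", "and", "did", "not") %in% toks))
})

test_that("preprocessing splits compounds, removes single letters, lemmatizes", {
  toks <- preprocess_text("Non-small-cell carcinomas: higher T counts in 5 patients.")
  expect_false(any(grepl("[[:punct:]]", toks)))
  expect_false(any(nchar(toks) == 1L & grepl("[a-z]", toks)))
  expect_true(all(c("non", "small", "cell", "carcinoma", "high", "count",
                    "patient") %in% toks))
  expect_identical(preprocess_text(""), character())
})

test_that("punctuation and lowercase stages are a fixed point on their own output; stop-word re-runs only remove acronym relics", {
  texts <- c(
    "EGFR-mutant tumors; ALL and AML were studied in all 10 patients.",
    "A higher response-rate was seen (p<0.05) after treatment!",
    "meshd002289 progressed despite ncbigene1956 inhibition."
  )
  stops <- kce_stopwords()
  for (tx in texts) {
    toks <- preprocess_text(tx, stops)
    rerun <- preprocess_text(paste(toks, collapse = " "), stops)
    removed <- setdiff(toks, rerun)
    # anything removed on a second pass must be a stop-list member that
    # survived the first pass only because it was an uppercase acronym
    expect_true(all(removed %in% stops))
    expect_true(all(rerun %in% toks))
    # punctuation deletion and lowercasing are exact fixed points
    expect_identical(toks, tolower(toks))
    expect_false(any(grepl("[^a-z0-9]", toks)))
  }
})

test_that("corpus write/read round-trips and prep_corpus ties the stages together", {
  h <- toy_hierarchy()
  arts <- rbind(
    make_article("1", "Kinase study", "EGFR inhibition in carcinomas.",
                 mesh = "D002289"),
    make_article("2", "Ignored", "", mesh = "D002289"))
  anns <- data.table::data.table(pmid = "1", start = 13L, end = 17L,
                                 category = "gene", concept_id = "1956")
  corp <- prep_corpus(arts, anns, h, "D009369")
  expect_equal(corp$pmid, "1")
  expect_true("ncbigene1956" %in% corp$tokens[[1]])
  path <- tempfile(fileext = ".gz")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_identical(back$tokens, corp$tokens)
  expect_identical(back$pmid, corp$pmid)
})
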