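# Shared fixture builders. Everything is constructed in code; nothing binary.

make_article <- function(pmid, title, abstract, year = 2005L,
                         mesh = character(), kw = character()) {
  data.table::data.table(pmid = pmid, year = as.integer(year),
                         mesh_ids = list(mesh), keywords = list(kw),
                         title = title, abstract = abstract)
}

# three-node hierarchy: neoplasms root with one child, plus a kinase root
toy_hierarchy <- function() {
  structure(list(
    D009369 = list(label = "Neoplasms", synonyms = c("Tumors", "Cancer"),
                   parents = character()),
    D011494 = list(label = "Protein Kinases", synonyms = character(),
                   parents = character()),
    D008175 = list(label = "Lung Neoplasms", synonyms = "lung cancer",
                   parents = "D009369"),
    D002289 = list(label = "Carcinoma, Non-Small-Cell Lung",
                   synonyms = "NSCLC", parents = "D008175")
  ), class = "kce_mesh")
}

# deterministic toy corpus as a list of token vectors
toy_corpus <- function() {
  list(
    c("meshd001", "ncbigene1", "treatment", "response"),
    c("ncbigene1", "meshd001", "treatment"),
    c("meshd002", "pathway", "cell"),
    c("ncbigene2", "cell", "pathway", "meshd002"),
    c("treatment", "cell", "response")
  )
}

# corpus with planted co-occurrence: tokens a and b always co-occur (adjacent,
# inside their own topic vocabulary, as co-occurring words do in real text),
# while z lives in a disjoint topic and never shares a document with a
planted_corpus <- function(n_docs = 120L, seed = 5L) {
  withr::with_seed(seed, {
    topic_ab <- sprintf("f%02d", 1:6)
    topic_z <- sprintf("g%02d", 1:6)
    docs <- list()
    for (i in seq_len(n_docs)) {
      if (i %% 2L == 0L) {
        docs[[i]] <- c(sample(topic_ab, 3), "a", "b", sample(topic_ab, 3))
      } else {
        docs[[i]] <- c(sample(topic_z, 3), "z", sample(topic_z, 3))
      }
    }
    docs
  })
}

# small labeled feature set that is linearly separable on dimension 1
separable_features <- function(n_pos = 15L, n_neg = 30L, dim = 6L, seed = 3L) {
  withr::with_seed(seed, {
    x <- rbind(
      cbind(matrix(rnorm(n_pos * (dim - 1), sd = 0.3), n_pos), rnorm(n_pos, 3, 0.2)),
      cbind(matrix(rnorm(n_neg * (dim - 1), sd = 0.3), n_neg), rnorm(n_neg, -3, 0.2))
    )
    x <- x[, c(dim, seq_len(dim - 1))]
    pairs <- data.table::data.table(
      pk = sprintf("PK%02d", seq_len(n_pos + n_neg)),
      cancer = sprintf("C%02d", seq_len(n_pos + n_neg)),
      label = c(rep(1L, n_pos), rep(0L, n_neg))
    )
    structure(list(pairs = pairs, x = x), class = "kce_features")
  })
}

# brute-force AUROC: concordant (positive, negative) pairs with half-credit
# for ties
auroc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force average precision: step-weighted sum over descending distinct
# score thresholds
ap_stepsum <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0
  ap <- 0
  P <- sum(labels == 1)
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    ap <- ap + (rec - prev_r) * prec
    prev_r <- rec
  }
  ap
}

pair_key_test <- function(tab) paste(tab$pk, tab$cancer, sep = "|")

# tiny evidence table builder
ev_row <- function(pk, cancer, phase, year, nct = "NCT1", pki = "PKI1") {
  data.table::data.table(pk = pk, cancer = cancer, phase = phase,
                         start_year = as.integer(year), nct_id = nct, pki = pki)
}

# the 12-document fixture used throughout: three kinases, three cancers
baseline_fixture <- function() {
  list(
    pk_tokens = list(K1 = "ncbigene1", K2 = "ncbigene2", K3 = "ncbigene3"),
    cancer_tokens = list(C1 = "meshd1", C2 = "meshd2", C3 = "meshd3"),
    corpus = list(
      c("ncbigene1", "meshd1", "w1"),
      c("ncbigene1", "meshd1", "w2"),
      c("ncbigene1", "ncbigene1", "meshd1"),   # repeats still count once
      c("ncbigene1", "meshd2"),
      c("ncbigene2", "meshd2", "w3"),
      c("ncbigene2", "w4"),
      c("meshd3", "w5"),
      c("ncbigene3", "meshd3", "meshd1"),      # two cancers in one abstract
      c("w6", "w7"),
      c("ncbigene2", "meshd2"),
      c("ncbigene1", "w8", "meshd1"),
      c("ncbigene3", "w9")
    )
  )
}
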