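#' Count document-level co-occurrence of kinase and cancer concepts
#'
#' A pair co-occurs in a document when the document contains at least one
#' token for the kinase and at least one token for the cancer; the count is
#' the number of such documents (document-level counting: multiple mentions
#' inside one abstract still count once). Pairs never co-occurring are absent
#' from the result (implicit zero).
#'
#' @param corpus Corpus table (`pmid`, `tokens`) or list of token vectors.
#' @param pk_tokens Named list (or named character vector) mapping each
#'   kinase identifier to its concept token(s).
#' @param cancer_tokens Same for cancers.
#' @return `data.table` with columns `pk`, `cancer`, `count` (documents).
#' @export
count_cooccurrence <- function(corpus, pk_tokens, cancer_tokens) {
  toks <- corpus_token_list(corpus)
  pk_tokens <- lapply(as.list(pk_tokens), as.character)
  cancer_tokens <- lapply(as.list(cancer_tokens), as.character)
  counts <- new.env(parent = emptyenv())
  for (doc in toks) {
    doc <- unique(doc)
    pks_in <- names(pk_tokens)[vapply(pk_tokens, function(t) any(t %in% doc),
                                      logical(1))]
    if (length(pks_in) == 0L) next
    cas_in <- names(cancer_tokens)[vapply(cancer_tokens,
                                          function(t) any(t %in% doc),
                                          logical(1))]
    for (p in pks_in) for (ca in cas_in) {
      k <- pair_key(p, ca)
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  out <- pair_unkey(keys)
  out[, count := vapply(keys, function(k) counts[[k]], integer(1))]
  setorderv(out, c("pk", "cancer"))
  out[]
}

#' Sweep the co-occurrence threshold and report precision/recall/F1
#'
#' For each threshold k in `[k_min, k_max]` a pair is predicted positive when
#' its co-occurrence count is at least k; the confusion matrix against the
#' labeled positive and negative pair sets yields precision, recall and F1
#' (all set to 0 when undefined). The maximizing k and its F1 are attached as
#' attributes `best_k` and `max_f1`.
#'
#' @param counts Count table from [count_cooccurrence()].
#' @param positives,negatives Disjoint pair tables (`pk`, `cancer`).
#' @param k_min,k_max Threshold range (defaults 1 and 25).
#' @return `data.table` with columns `k`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`.
#' @export
baseline_sweep <- function(counts, positives, negatives, k_min = 1L,
                           k_max = 25L) {
  k_min <- check_count(k_min, "k_min")
  k_max <- check_count(k_max, "k_max", min = k_min)
  pos_keys <- pair_key(positives$pk, positives$cancer)
  neg_keys <- pair_key(negatives$pk, negatives$cancer)
  if (length(intersect(pos_keys, neg_keys)) > 0L) {
    kce_stop("positive and negative pair sets overlap", "kce_validation_error")
  }
  cnt <- stats::setNames(counts$count, pair_key(counts$pk, counts$cancer))
  count_of <- function(keys) {
    v <- cnt[keys]
    v[is.na(v)] <- 0L
    unname(v)
  }
  pos_cnt <- count_of(pos_keys)
  neg_cnt <- count_of(neg_keys)
  rows <- lapply(seq.int(k_min, k_max), function(k) {
    tp <- sum(pos_cnt >= k)
    fn <- length(pos_cnt) - tp
    fp <- sum(neg_cnt >= k)
    tn <- length(neg_cnt) - fp
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.table(k = k, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = precision, recall = recall, f1 = f1)
  })
  out <- rbindlist(rows)
  best <- which.max(out$f1)
  attr(out, "best_k") <- out$k[best]
  attr(out, "max_f1") <- out$f1[best]
  out[]
}
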