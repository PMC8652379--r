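#' Configuration for skip-gram negative-sampling training
#'
#' Defaults follow the hyperparameters used for the kinase-cancer corpus:
#' context radius 5, minimum token frequency 5, mini-batch size 128, 20 noise
#' samples per positive pair, 100 dimensions. Epochs (5) and the initial
#' learning rate (0.025, linearly decayed) are conventional word2vec defaults;
#' frequent-word subsampling and the shrinking (dynamic) window variant exist
#' as toggles and default off.
#'
#' @param window Integer context radius.
#' @param min_count Frequency floor for the vocabulary.
#' @param batch_size Pairs per mini-batch update.
#' @param negatives Noise samples per positive pair.
#' @param dim Embedding dimension.
#' @param epochs Training epochs.
#' @param learning_rate Initial learning rate (linear decay to 1e-4 of it).
#' @param subsample Frequent-word subsampling threshold; 0 disables.
#' @param dynamic_window If `TRUE`, the effective radius is drawn uniformly
#'   from 1..`window` per center token (word2vec's shrinking window).
#' @param seed Integer seed; training is bit-reproducible for a fixed seed.
#' @return An object of class `kce_embedding_config`.
#' @export
embedding_config <- function(window = 5L, min_count = 5L, batch_size = 128L,
                             negatives = 20L, dim = 100L, epochs = 5L,
                             learning_rate = 0.025, subsample = 0,
                             dynamic_window = FALSE, seed = 1L) {
  cfg <- list(
    window = check_count(window, "window"),
    min_count = check_count(min_count, "min_count"),
    batch_size = check_count(batch_size, "batch_size"),
    negatives = check_count(negatives, "negatives"),
    dim = check_count(dim, "dim", min = 2L),
    epochs = check_count(epochs, "epochs"),
    learning_rate = learning_rate,
    subsample = subsample,
    dynamic_window = isTRUE(dynamic_window),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L ||
      learning_rate <= 0) {
    kce_stop("`learning_rate` must be a positive number", "kce_config_error")
  }
  structure(cfg, class = "kce_embedding_config")
}

#' Build the token vocabulary of a corpus
#'
#' Counts token frequencies over all documents and keeps tokens whose
#' frequency is at least `min_count`. Index assignment is deterministic: by
#' descending frequency, ties broken by token string.
#'
#' @param corpus Corpus table (`pmid`, `tokens`) from [read_corpus()] or
#'   [prep_corpus()], or a plain list of token vectors.
#' @param min_count Frequency floor.
#' @return A `data.table` with columns `token`, `freq`, `index` (1-based).
#' @export
build_vocabulary <- function(corpus, min_count = 5L) {
  min_count <- check_count(min_count, "min_count")
  toks <- corpus_token_list(corpus)
  all_tokens <- unlist(toks, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    return(data.table(token = character(), freq = integer(), index = integer()))
  }
  tab <- as.data.table(table(token = all_tokens))
  setnames(tab, c("token", "freq"))
  tab[, freq := as.integer(freq)]
  tab <- tab[freq >= min_count]
  setorderv(tab, c("freq", "token"), order = c(-1L, 1L))
  tab[, index := seq_len(.N)]
  tab[]
}

corpus_token_list <- function(corpus) {
  if (is.data.frame(corpus)) corpus$tokens else corpus
}

#' Train skip-gram negative-sampling embeddings
#'
#' Optimizes, by mini-batch gradient ascent, the objective
#' \deqn{\log\sigma(u_o \cdot v_c) + \sum_{i=1}^{K}\log\sigma(-u_{n_i}\cdot v_c)}
#' over all (center, context) pairs within the window, with noise tokens
#' drawn from the unigram distribution raised to the 0.75 power. Input vectors
#' are initialized uniformly in \eqn{[-0.5/dim, 0.5/dim]}, output vectors at
#' zero. Training is single-threaded and fully reproducible for a fixed seed.
#' The map f(token) served by [embedding_vector()] is the input-vector matrix;
#' output vectors are retained only for training.
#'
#' @param corpus Corpus table or list of token vectors.
#' @param config An [embedding_config()].
#' @return An object of class `kce_embedding`: list with `vocabulary`
#'   (the [build_vocabulary()] table), `input` and `output` (numeric matrices,
#'   one row per vocabulary token, `dim` columns, rownames = tokens),
#'   `epoch_loss` (mean negative objective per epoch) and `config`.
#' @export
train_skipgram <- function(corpus, config = embedding_config()) {
  if (!inherits(config, "kce_embedding_config")) {
    kce_stop("`config` must come from embedding_config()", "kce_config_error")
  }
  vocab <- build_vocabulary(corpus, config$min_count)
  if (nrow(vocab) == 0L) {
    kce_stop("vocabulary is empty after applying min_count", "kce_config_error")
  }
  toks <- corpus_token_list(corpus)
  idx <- stats::setNames(vocab$index, vocab$token)
  docs <- lapply(toks, function(tk) {
    m <- idx[tk]
    as.integer(m[!is.na(m)] - 1L)
  })
  docs <- docs[lengths(docs) > 1L]
  fit <- .sgns_train_cpp(docs, as.numeric(vocab$freq), config$window,
                         config$dim, config$negatives, config$batch_size,
                         config$epochs, config$learning_rate, config$subsample,
                         config$dynamic_window, as.numeric(config$seed))
  rownames(fit$input) <- vocab$token
  rownames(fit$output) <- vocab$token
  structure(
    list(vocabulary = vocab, input = fit$input, output = fit$output,
         epoch_loss = as.numeric(fit$epoch_loss), config = config),
    class = "kce_embedding"
  )
}

#' @export
print.kce_embedding <- function(x, ...) {
  cat(sprintf("kce_embedding: %d tokens x %d dimensions (min_count=%d, window=%d)\n",
              nrow(x$input), ncol(x$input), x$config$min_count, x$config$window))
  invisible(x)
}

#' Look up the embedding of a token
#'
#' @param model A `kce_embedding` from [train_skipgram()] or
#'   [read_embeddings()].
#' @param token A single token string.
#' @return Numeric vector of length `dim`.
#' @export
embedding_vector <- function(model, token) {
  stopifnot(inherits(model, "kce_embedding"))
  i <- match(token, rownames(model$input))
  if (is.na(i)) {
    kce_stop(sprintf("token not in vocabulary: %s", token),
             "kce_missing_token", token = token)
  }
  model$input[i, ]
}

#' Cosine similarity between two vectors
#' @param u,v Numeric vectors of equal length.
#' @return `sum(u*v) / (||u|| ||v||)`.
#' @export
cosine_similarity <- function(u, v) {
  sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
}

#' Per-pair skip-gram objective and analytic gradients (reference form)
#'
#' Pure-R statement of the negative-sampling objective for one
#' (center, context) pair and its gradients:
#' objective \eqn{\log\sigma(u_o\cdot v_c) + \sum_i \log\sigma(-u_{n_i}\cdot v_c)},
#' gradient w.r.t. the center vector
#' \eqn{(1-\sigma(u_o\cdot v_c))u_o - \sum_i \sigma(u_{n_i}\cdot v_c)u_{n_i}},
#' and correspondingly for the context and noise vectors. This is the
#' mathematical contract the compiled trainer implements; it is exercised
#' against numerical differentiation in the test suite.
#'
#' @param v_c Center (input) vector.
#' @param u_o Context (output) vector.
#' @param u_neg Matrix of noise (output) vectors, one per row.
#' @return List with `objective`, `grad_center`, `grad_context`,
#'   `grad_negatives` (matrix, same shape as `u_neg`).
#' @export
sgns_pair_gradient <- function(v_c, u_o, u_neg) {
  sigm <- function(x) 1 / (1 + exp(-x))
  s_o <- sigm(sum(u_o * v_c))
  s_n <- sigm(as.numeric(u_neg %*% v_c))
  list(
    objective = log(s_o) + sum(log(1 - s_n)),
    grad_center = (1 - s_o) * u_o - as.numeric(t(u_neg) %*% s_n),
    grad_context = (1 - s_o) * v_c,
    grad_negatives = -s_n %o% v_c
  )
}

#' Write / read embeddings in word2vec text format
#'
#' Header line `"N dim"`, then one line per token: the token followed by
#' `dim` decimal floats. Reading returns a `kce_embedding` whose `output`
#' matrix and training metadata are absent (lookup-only model).
#'
#' @param model A `kce_embedding`.
#' @param path Output (or input) path; `.gz` handled transparently.
#' @export
write_embeddings <- function(model, path) {
  stopifnot(inherits(model, "kce_embedding"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$input), ncol(model$input)), con)
  lines <- vapply(seq_len(nrow(model$input)), function(i) {
    paste(c(rownames(model$input)[i],
            formatC(model$input[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  header <- strsplit(readLines(con, n = 1L), " ")[[1]]
  n <- as.integer(header[1]); d <- as.integer(header[2])
  lines <- readLines(con, warn = FALSE)
  parts <- strsplit(lines[nzchar(lines)], " ", fixed = TRUE)
  if (length(parts) != n) {
    kce_stop(sprintf("embedding file declares %d tokens but has %d rows",
                     n, length(parts)), "kce_parse_error")
  }
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(mat) <- vapply(parts, `[`, character(1), 1L)
  vocab <- data.table(token = rownames(mat), freq = NA_integer_,
                      index = seq_len(n))
  structure(list(vocabulary = vocab, input = mat, output = NULL,
                 epoch_loss = NULL, config = NULL),
            class = "kce_embedding")
}
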