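#' Difference-vector features for kinase-cancer pairs
#'
#' The feature of a candidate pair is the componentwise difference
#' `f(pk_token) - f(cancer_token)` between the two concept embeddings. Pairs
#' whose tokens are unresolvable or missing from the vocabulary are dropped
#' with a message; an error is raised only when no pair survives.
#'
#' @param pairs Pair table with columns `pk`, `cancer` and optionally `label`.
#' @param model A `kce_embedding`.
#' @param pk_token_map,cancer_token_map Named character vectors mapping
#'   identifiers to concept tokens, or `NULL` when the identifiers already
#'   are tokens.
#' @return An object of class `kce_features`: list with `pairs` (a
#'   `data.table` of `pk`, `cancer`, `label`, deterministically sorted by
#'   `pk` then `cancer`) and `x` (numeric matrix, one row per pair).
#' @export
build_difference_features <- function(pairs, model, pk_token_map = NULL,
                                      cancer_token_map = NULL) {
  pairs <- as.data.table(pairs)
  if (!"label" %in% names(pairs)) pairs[, label := NA_integer_]
  setorderv(pairs, c("pk", "cancer"))
  map_tok <- function(ids, map) {
    if (is.null(map)) ids else unname(map[ids])
  }
  pk_tok <- map_tok(pairs$pk, pk_token_map)
  ca_tok <- map_tok(pairs$cancer, cancer_token_map)
  vocab <- rownames(model$input)
  ok <- !is.na(pk_tok) & !is.na(ca_tok) & pk_tok %in% vocab & ca_tok %in% vocab
  if (!all(ok)) {
    message(sprintf("build_difference_features: dropping %d/%d pairs without embeddings",
                    sum(!ok), length(ok)))
  }
  if (!any(ok)) {
    kce_stop("no pair could be featurized (all tokens unresolvable)",
             "kce_empty_features_error")
  }
  pairs <- pairs[ok]
  x <- model$input[match(pk_tok[ok], vocab), , drop = FALSE] -
    model$input[match(ca_tok[ok], vocab), , drop = FALSE]
  rownames(x) <- NULL
  structure(list(pairs = pairs[, .(pk, cancer, label)], x = x),
            class = "kce_features")
}

#' Randomized-search space for the random forest
#'
#' Ranges for the forest hyperparameters: number of trees, maximum features
#' per split (`"sqrt"`, `"log2"` or a fraction of the feature count), maximum
#' tree depth (0 = unlimited), minimum node size, and whether bootstrap
#' resampling is used. `iterations` configurations are drawn uniformly
#' without replacement from the grid (the whole grid is scanned when it has
#' at most `iterations` points) and scored by `cv_folds`-fold cross-validated
#' AUROC.
#'
#' @param num_trees,max_depth,min_node_size Integer vectors of candidate values.
#' @param max_features Vector mixing `"sqrt"`, `"log2"` and numeric fractions.
#' @param bootstrap Logical candidates.
#' @param iterations Number of configurations to evaluate.
#' @param cv_folds Cross-validation folds.
#' @param seed Integer seed governing sampling, folds and forest fits.
#' @return An object of class `kce_search_space`.
#' @export
search_space <- function(num_trees = seq(100L, 1000L, by = 100L),
                         max_features = c("sqrt", "log2",
                                          as.character(seq(0.1, 1, by = 0.1))),
                         max_depth = c(0L, seq(10L, 100L, by = 10L)),
                         min_node_size = c(1L, 2L, 4L),
                         bootstrap = c(TRUE, FALSE),
                         iterations = 100L, cv_folds = 5L, seed = 1L) {
  ranges <- list(num_trees = num_trees, max_features = as.character(max_features),
                 max_depth = max_depth, min_node_size = min_node_size,
                 bootstrap = bootstrap)
  if (any(lengths(ranges) == 0L)) {
    kce_stop("every hyperparameter range must be non-empty", "kce_config_error")
  }
  structure(list(ranges = ranges,
                 iterations = check_count(iterations, "iterations"),
                 cv_folds = check_count(cv_folds, "cv_folds", min = 2L),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "kce_search_space")
}

# decode grid point `i` (1-based) of the mixed-radix configuration grid
decode_config <- function(ranges, i) {
  i <- i - 1L
  cfg <- list()
  for (nm in names(ranges)) {
    k <- length(ranges[[nm]])
    cfg[[nm]] <- ranges[[nm]][(i %% k) + 1L]
    i <- i %/% k
  }
  cfg
}

resolve_mtry <- function(max_features, p) {
  if (max_features == "sqrt") return(max(1L, floor(sqrt(p))))
  if (max_features == "log2") return(max(1L, floor(log2(p))))
  max(1L, min(p, floor(as.numeric(max_features) * p)))
}

fit_forest <- function(x, y, cfg, seed) {
  dat <- as.data.frame(x)
  dat$..y <- factor(y, levels = c(0L, 1L))
  ranger::ranger(
    dependent.variable.name = "..y", data = dat,
    num.trees = cfg$num_trees,
    mtry = resolve_mtry(cfg$max_features, ncol(x)),
    max.depth = cfg$max_depth,
    min.node.size = cfg$min_node_size,
    replace = cfg$bootstrap,
    sample.fraction = if (cfg$bootstrap) 1 else 0.632,
    probability = TRUE, num.threads = 1L, seed = seed,
    verbose = FALSE
  )
}

forest_scores <- function(fit, x) {
  pred <- predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions
  as.numeric(pred[, "1"])
}

#' Train the random forest with randomized hyperparameter search
#'
#' Draws configurations uniformly without replacement from the search grid,
#' scores each by cross-validated AUROC (stratified folds), selects the best
#' configuration (ties broken by grid order) and refits it on all training
#' rows. Fully reproducible for a fixed search-space seed.
#'
#' @param train_rows A `kce_features` object with 0/1 labels, both classes
#'   present.
#' @param space A [search_space()].
#' @return An object of class `kce_classifier`: list with the fitted `forest`,
#'   `best_config`, `cv_auroc` of the best configuration, `search` (table of
#'   all evaluated configurations and scores) and `dim`.
#' @export
train_classifier <- function(train_rows, space = search_space()) {
  stopifnot(inherits(train_rows, "kce_features"))
  y <- train_rows$pairs$label
  if (length(unique(y)) < 2L) {
    kce_stop("training rows must contain both classes", "kce_training_error")
  }
  x <- train_rows$x
  ranges <- space$ranges
  total <- prod(lengths(ranges))
  n_eval <- min(space$iterations, total)
  picked <- withr::with_seed(space$seed, {
    if (n_eval >= total) seq_len(total) else sample.int(total, n_eval)
  })
  folds <- withr::with_seed(space$seed + 1L, stratified_folds(y, space$cv_folds))
  results <- vector("list", n_eval)
  for (j in seq_len(n_eval)) {
    cfg <- decode_config(ranges, picked[j])
    aucs <- vapply(seq_len(space$cv_folds), function(f) {
      tr <- folds != f
      te <- !tr
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- fit_forest(x[tr, , drop = FALSE], y[tr], cfg,
                        seed = space$seed + 1000L + j)
      ev <- evaluate(forest_scores(fit, x[te, , drop = FALSE]), y[te])
      ev$auroc
    }, numeric(1))
    results[[j]] <- data.table(grid_index = picked[j],
                               num_trees = cfg$num_trees,
                               max_features = cfg$max_features,
                               max_depth = cfg$max_depth,
                               min_node_size = cfg$min_node_size,
                               bootstrap = cfg$bootstrap,
                               cv_auroc = mean(aucs, na.rm = TRUE))
  }
  search <- rbindlist(results)
  best_j <- which.max(search$cv_auroc) # first (lowest grid order) on ties
  best_cfg <- decode_config(ranges, search$grid_index[best_j])
  forest <- fit_forest(x, y, best_cfg, seed = space$seed + 999L)
  structure(list(forest = forest, best_config = best_cfg,
                 cv_auroc = search$cv_auroc[best_j], search = search,
                 dim = ncol(x), space = space),
            class = "kce_classifier")
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    i <- which(y == cls)
    folds[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  folds
}

#' @export
print.kce_classifier <- function(x, ...) {
  cat(sprintf("kce_classifier: random forest on %d-dim difference vectors\n",
              x$dim))
  cat(sprintf("  best config: %d trees, max_features=%s, max_depth=%d, min_node_size=%d, bootstrap=%s\n",
              x$best_config$num_trees, x$best_config$max_features,
              x$best_config$max_depth, x$best_config$min_node_size,
              x$best_config$bootstrap))
  cat(sprintf("  cross-validated AUROC: %.3f\n", x$cv_auroc))
  invisible(x)
}

#' Score pairs with a fitted classifier
#'
#' @param model A `kce_classifier`.
#' @param rows A `kce_features` object (same feature dimension).
#' @return Numeric vector of positive-class probabilities (tree-vote
#'   fractions) in `[0, 1]`, one per row, order preserved.
#' @export
score_pairs <- function(model, rows) {
  stopifnot(inherits(model, "kce_classifier"), inherits(rows, "kce_features"))
  if (ncol(rows$x) != model$dim) {
    kce_stop(sprintf("feature dimension mismatch: model %d, rows %d",
                     model$dim, ncol(rows$x)), "kce_dim_error")
  }
  forest_scores(model$forest, rows$x)
}

#' ROC / PR evaluation of scored pairs
#'
#' Sweeps a threshold over the distinct scores (predicting positive at
#' `score >= threshold`). The ROC curve starts at (0, 0) and ends at (1, 1);
#' AUROC is its trapezoidal area. Average precision is the step-weighted sum
#' \eqn{\sum_k (R_k - R_{k-1}) P_k} over the precision-recall curve.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return An object of class `kce_evaluation`: list with `roc`
#'   (`data.table` of `fpr`, `tpr`, `threshold`), `pr` (`recall`, `precision`,
#'   `threshold`), `auroc`, `average_precision`, and `thresholds`
#'   (list with `gmean` and `f1_opt`).
#' @export
evaluate <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    kce_stop("`scores` and `labels` must have equal length", "kce_eval_error")
  }
  if (length(unique(labels)) < 2L) {
    kce_stop("labels must contain both classes", "kce_eval_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  # last index of each tie-group of equal scores
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  thr <- s[last]
  roc <- data.table(fpr = c(0, fp / N), tpr = c(0, tp / P),
                    threshold = c(Inf, thr))
  pr <- data.table(recall = tp / P, precision = tp / (tp + fp),
                   threshold = thr)
  auroc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  ap <- sum(diff(c(0, pr$recall)) * pr$precision)
  rep <- structure(list(roc = roc, pr = pr, auroc = auroc,
                        average_precision = ap, thresholds = NULL),
                   class = "kce_evaluation")
  rep$thresholds <- list(gmean = select_threshold(rep, "gmean"),
                         f1_opt = select_threshold(rep, "f1_opt"))
  rep
}

#' @export
print.kce_evaluation <- function(x, ...) {
  cat(sprintf("kce_evaluation: AUROC %.3f, average precision %.3f\n",
              x$auroc, x$average_precision))
  cat(sprintf("  thresholds: gmean %.4f, F1-optimal %.4f\n",
              x$thresholds$gmean, x$thresholds$f1_opt))
  invisible(x)
}

#' Select a decision threshold from an evaluation
#'
#' `"gmean"` returns the threshold maximizing the geometric mean of
#' sensitivity and specificity, `sqrt(TPR * (1 - FPR))`, over the ROC curve;
#' `"f1_opt"` the threshold maximizing F1 over the PR curve. Ties return the
#' smallest threshold.
#'
#' @param report A `kce_evaluation` from [evaluate()].
#' @param criterion `"gmean"` or `"f1_opt"`.
#' @return The selected threshold (a score value).
#' @export
select_threshold <- function(report, criterion = c("gmean", "f1_opt")) {
  criterion <- match.arg(criterion)
  if (criterion == "gmean") {
    curve <- report$roc[is.finite(threshold)]
    val <- sqrt(curve$tpr * (1 - curve$fpr))
  } else {
    curve <- report$pr[is.finite(threshold)]
    p <- curve$precision
    r <- curve$recall
    val <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  }
  best <- val == max(val)
  min(curve$threshold[best])
}

#' Rank de-novo predictions
#'
#' Scores every universe pair, sorts by descending score (ties by pk, then
#' cancer) and flags rows at or above the threshold.
#'
#' @param model A `kce_classifier`.
#' @param universe_rows A `kce_features` object for the prediction universe.
#' @param threshold Decision threshold (e.g. from [select_threshold()]).
#' @return `data.table` with `rank`, `pk`, `cancer`, `score`,
#'   `above_threshold`.
#' @export
rank_predictions <- function(model, universe_rows, threshold) {
  sc <- score_pairs(model, universe_rows)
  out <- data.table(pk = universe_rows$pairs$pk,
                    cancer = universe_rows$pairs$cancer,
                    score = sc)
  setorderv(out, c("score", "pk", "cancer"), order = c(-1L, 1L, 1L))
  out[, rank := seq_len(.N)]
  out[, above_threshold := score >= threshold]
  out[, .(rank, pk, cancer, score, above_threshold)]
}
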