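toy_embedding <- function() {
  mat <- rbind(
    pk_a = c(1, 0, 2, -1),
    pk_b = c(0.5, 0.5, 0.5, 0.5),
    ca_x = c(1, 0, 2, -1),
    ca_y = c(-1, 2, 0, 3)
  )
  structure(list(
    vocabulary = data.table::data.table(token = rownames(mat), freq = 10L,
                                        index = 1:4),
    input = mat, output = NULL, epoch_loss = NULL, config = NULL),
    class = "kce_embedding")
}

test_that("difference features are hand-computable, antisymmetric, and zero for equal vectors", {
  emb <- toy_embedding()
  pairs <- data.table::data.table(pk = c("A", "A", "B"),
                                  cancer = c("X", "Y", "Y"),
                                  label = c(1L, 0L, 0L))
  pmap <- c(A = "pk_a", B = "pk_b")
  cmap <- c(X = "ca_x", Y = "ca_y")
  fr <- build_difference_features(pairs, emb, pmap, cmap)
  # rows sorted by (pk, cancer); hand-computed differences
  expect_equal(fr$pairs$pk, c("A", "A", "B"))
  expect_equal(unname(fr$x[1, ]), c(0, 0, 0, 0))              # pk_a - ca_x
  expect_equal(unname(fr$x[2, ]), c(2, -2, 2, -4))            # pk_a - ca_y
  expect_equal(unname(fr$x[3, ]), c(1.5, -1.5, 0.5, -2.5))    # pk_b - ca_y
  # swapping subtraction order negates every component
  rev <- build_difference_features(
    data.table::data.table(pk = "A", cancer = "Y", label = 0L),
    emb, c(A = "ca_y"), c(Y = "pk_a"))
  expect_equal(unname(rev$x[1, ]), -unname(fr$x[2, ]))
})

test_that("pairs without embeddings are dropped; losing all pairs is an error", {
  emb <- toy_embedding()
  pairs <- data.table::data.table(pk = c("pk_a", "ZZ"), cancer = c("ca_x", "ca_x"),
                                  label = c(1L, 0L))
  expect_message(fr <- build_difference_features(pairs, emb), "dropping 1/2")
  expect_equal(nrow(fr$pairs), 1L)
  all_bad <- data.table::data.table(pk = "ZZ", cancer = "QQ", label = 1L)
  expect_error(suppressMessages(build_difference_features(all_bad, emb)),
               class = "kce_empty_features_error")
})

test_that("the forest separates a separable toy problem and is seed-deterministic", {
  fr <- separable_features()
  space <- search_space(num_trees = c(100L, 200L), max_features = "sqrt",
                        max_depth = 0L, min_node_size = c(1L, 2L),
                        bootstrap = TRUE, iterations = 4L, cv_folds = 3L,
                        seed = 2L)
  m1 <- train_classifier(fr, space)
  m2 <- train_classifier(fr, space)
  expect_identical(m1$best_config, m2$best_config)
  s1 <- score_pairs(m1, fr)
  expect_identical(s1, score_pairs(m2, fr))
  expect_equal(evaluate(s1, fr$pairs$label)$auroc, 1.0)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_true(min(s1[fr$pairs$label == 1]) > max(s1[fr$pairs$label == 0]))
})

test_that("randomized search over a small grid equals the exhaustive arg-max", {
  fr <- separable_features(n_pos = 12L, n_neg = 24L)
  ranges <- list(num_trees = c(50L, 150L), max_features = c("sqrt", "0.9"))
  space <- search_space(num_trees = ranges$num_trees,
                        max_features = ranges$max_features,
                        max_depth = 0L, min_node_size = 1L, bootstrap = TRUE,
                        iterations = 10L, cv_folds = 3L, seed = 9L)
  m <- train_classifier(fr, space)
  # every grid point was evaluated (4 points, iterations >= 4, no replacement)
  expect_equal(nrow(m$search), 4L)
  expect_equal(anyDuplicated(m$search$grid_index), 0L)
  best <- m$search[which.max(m$search$cv_auroc)]
  expect_equal(m$best_config$num_trees, best$num_trees)
  expect_equal(m$best_config$max_features, best$max_features)
  expect_equal(m$cv_auroc, max(m$search$cv_auroc))
})

test_that("single-class training input and dimension mismatches are errors", {
  fr <- separable_features()
  fr$pairs$label <- 1L
  expect_error(train_classifier(fr), class = "kce_training_error")
  fr2 <- separable_features()
  m <- train_classifier(fr2, search_space(num_trees = 100L,
                                          max_features = "sqrt",
                                          max_depth = 0L, min_node_size = 1L,
                                          bootstrap = TRUE, iterations = 1L,
                                          cv_folds = 3L, seed = 1L))
  bad <- fr2
  bad$x <- bad$x[, 1:3]
  expect_error(score_pairs(m, bad), class = "kce_dim_error")
  # batch scoring equals row-by-row scoring
  sc <- score_pairs(m, fr2)
  one_by_one <- vapply(seq_len(nrow(fr2$x)), function(i) {
    r <- structure(list(pairs = fr2$pairs[i], x = fr2$x[i, , drop = FALSE]),
                   class = "kce_features")
    score_pairs(m, r)
  }, numeric(1))
  expect_equal(sc, one_by_one)
})

test_that("evaluation handles perfect and uninformative classifiers", {
  lab <- c(1, 0, 1, 0, 0)
  perfect <- evaluate(lab, lab)
  expect_equal(perfect$auroc, 1.0)
  expect_equal(perfect$average_precision, 1.0)
  flat <- evaluate(rep(0.4, 5), lab)
  expect_equal(flat$auroc, 0.5)
  expect_error(evaluate(1:3, c(1, 1, 1)), class = "kce_eval_error")
  expect_error(evaluate(1:3, c(1, 0)), class = "kce_eval_error")
})

test_that("ROC curves span (0,0) to (1,1) and AUROC is their trapezoid area", {
  withr::with_seed(41, {
    sc <- runif(40)
    lb <- rbinom(40, 1, 0.3)
    lb[1:2] <- c(0, 1)
    ev <- evaluate(sc, lb)
    expect_equal(unlist(ev$roc[1, .(fpr, tpr)]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(ev$roc[.N, .(fpr, tpr)]), c(fpr = 1, tpr = 1))
    trap <- sum(diff(ev$roc$fpr) * (utils::head(ev$roc$tpr, -1) +
                                      ev$roc$tpr[-1]) / 2)
    expect_equal(ev$auroc, trap)
  })
})

test_that("AUROC equals pairwise concordance and AP equals the step sum on random instances", {
  withr::with_seed(13, {
    for (i in 1:50) {
      n <- 60
      sc <- round(runif(n), 2)  # rounding forces score ties
      lb <- rbinom(n, 1, 0.4)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
      ev <- evaluate(sc, lb)
      expect_equal(ev$auroc, auroc_concordance(sc, lb), tolerance = 1e-12)
      expect_equal(ev$average_precision, ap_stepsum(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("AUROC agrees with an independent ROC implementation", {
  withr::with_seed(19, {
    for (i in 1:5) {
      sc <- rnorm(80)
      lb <- rbinom(80, 1, 0.3)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
      ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                            direction = "<")))
      expect_equal(evaluate(sc, lb)$auroc, ref, tolerance = 1e-10)
    }
  })
})

test_that("AUROC is invariant under strictly increasing transforms and flips under negation", {
  withr::with_seed(29, {
    sc <- runif(50)
    lb <- rbinom(50, 1, 0.5)
    if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
    a <- evaluate(sc, lb)$auroc
    expect_equal(evaluate(exp(3 * sc) + 2, lb)$auroc, a)
    expect_equal(evaluate(-sc, lb)$auroc, 1 - a)
  })
})

test_that("threshold selection matches exhaustive scans and tie rules", {
  # gmean by exhaustive scan over all distinct scores
  withr::with_seed(37, {
    for (i in 1:20) {
      sc <- round(runif(30), 1)
      lb <- rbinom(30, 1, 0.4)
      if (length(unique(lb)) < 2) lb[1:2] <- c(0, 1)
      ev <- evaluate(sc, lb)
      scan <- function(metric) {
        thr <- sort(unique(sc))
        val <- vapply(thr, function(t) {
          pred <- as.integer(sc >= t)
          tp <- sum(pred & lb); fp <- sum(pred & !lb)
          fn <- sum(!pred & lb); tn <- sum(!pred & !lb)
          if (metric == "gmean") sqrt((tp / (tp + fn)) * (tn / (tn + fp)))
          else {
            p <- if (tp + fp > 0) tp / (tp + fp) else 0
            r <- tp / (tp + fn)
            if (p + r > 0) 2 * p * r / (p + r) else 0
          }
        }, numeric(1))
        min(thr[val == max(val)])
      }
      expect_equal(ev$thresholds$gmean, scan("gmean"))
      expect_equal(ev$thresholds$f1_opt, scan("f1"))
    }
  })
})

test_that("threshold selection on separable and one-point curves", {
  # perfectly separating scores: the smallest threshold attaining gmean 1 is
  # the lowest positive score
  ev <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$thresholds$gmean, 0.8)
  # single positive with the top score: the F1-optimal threshold is that score
  ev2 <- evaluate(c(0.9, 0.3, 0.2), c(1, 0, 0))
  expect_equal(ev2$thresholds$f1_opt, 0.9)
})

test_that("prediction ranking sorts, ranks and flags against the threshold", {
  fr <- separable_features()
  m <- train_classifier(fr, search_space(num_trees = 100L,
                                         max_features = "sqrt", max_depth = 0L,
                                         min_node_size = 1L, bootstrap = TRUE,
                                         iterations = 1L, cv_folds = 3L,
                                         seed = 1L))
  tab <- rank_predictions(m, fr, threshold = 0.5)
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$score) <= 0))
  expect_equal(sum(tab$above_threshold), sum(tab$score >= 0.5))
  # top-10 equals a full-sort oracle
  ord <- order(-tab$score, tab$pk, tab$cancer)
  expect_identical(tab[1:10], tab[ord[1:10]])
  # a threshold above the maximum score flags nothing
  none <- rank_predictions(m, fr, threshold = max(tab$score) + 1)
  expect_equal(sum(none$above_threshold), 0L)
})
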