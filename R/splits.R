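#' Configuration of a historical train/test split
#'
#' The protocol trains on kinase-cancer pairs with phase-IV evidence up to a
#' target year and tests on pairs whose first trial evidence appears in a
#' later window, excluding pairs with any-phase evidence through the target
#' year. Negatives are sampled uniformly at `neg_ratio` times the positives.
#'
#' @param target_year Last year of evidence available for training.
#' @param test_window Integer vector `c(first_year, last_year)`,
#'   `first_year > target_year`.
#' @param test_phase_filter `"all_phases"` (a trial of any phase makes a test
#'   positive) or `"phase_iv_only"`.
#' @param neg_ratio Negatives sampled per positive (default 10).
#' @param seed Integer seed for negative sampling.
#' @return An object of class `kce_split_config`.
#' @export
split_config <- function(target_year, test_window,
                         test_phase_filter = c("all_phases", "phase_iv_only"),
                         neg_ratio = 10L, seed = 1L) {
  test_phase_filter <- match.arg(test_phase_filter)
  target_year <- check_count(target_year, "target_year", min = 0L)
  if (length(test_window) != 2L || test_window[1] > test_window[2]) {
    kce_stop("`test_window` must be c(first_year, last_year) with first <= last",
             "kce_config_error")
  }
  if (test_window[1] <= target_year) {
    kce_stop("`test_window` must start after `target_year`", "kce_config_error")
  }
  structure(list(target_year = target_year,
                 test_window = as.integer(test_window),
                 test_phase_filter = test_phase_filter,
                 neg_ratio = check_count(neg_ratio, "neg_ratio"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "kce_split_config")
}

#' Positive training pairs: phase-IV evidence up to the target year
#'
#' Only phase IV counts for training, regardless of the test phase filter: a
#' post-approval trial is the evidence that inhibiting the kinase treats the
#' cancer. The trial year used against the cutoff is the start year.
#'
#' @param evidence Evidence table from [derive_pair_evidence()].
#' @param config A [split_config()].
#' @return `data.table` with columns `pk`, `cancer` (unique pairs, sorted).
#' @export
build_positive_train <- function(evidence, config) {
  ev <- as.data.table(evidence)
  pos <- unique(ev[as.character(phase) == "IV" & start_year <= config$target_year,
                   .(pk, cancer)])
  setorderv(pos, c("pk", "cancer"))
  pos[]
}

#' Uniform negative sampling without replacement
#'
#' Samples exactly `size` pairs uniformly from `universe` minus `excluded`,
#' reproducibly for a given seed (an isolated RNG stream; the caller's RNG
#' state is untouched).
#'
#' @param universe Pair table (`pk`, `cancer`) of candidate pairs.
#' @param excluded Pair table of pairs that must not be sampled.
#' @param size Number of pairs to draw.
#' @param seed Integer seed.
#' @return `data.table` with `pk`, `cancer` of `size` rows.
#' @export
sample_negative_set <- function(universe, excluded, size, seed) {
  size <- check_count(size, "size", min = 0L)
  cand <- setdiff(pair_key(universe$pk, universe$cancer),
                  pair_key(excluded$pk, excluded$cancer))
  if (length(cand) < size) {
    kce_stop(sprintf("cannot sample %d negatives from %d candidates (short by %d)",
                     size, length(cand), size - length(cand)),
             "kce_sizing_error", shortfall = size - length(cand))
  }
  cand <- sort(cand)
  picked <- withr::with_seed(seed, sample(cand, size))
  out <- pair_unkey(picked)
  setorderv(out, c("pk", "cancer"))
  out[]
}

#' Test sets for the historical protocol
#'
#' Test positives are pairs whose first qualifying evidence (any phase, or
#' phase IV only, per the config) starts inside the test window, that have no
#' evidence of any phase up to the target year, and that are not in the
#' drug-derived exclusion set (pairs obtainable from any inhibitor-kinase
#' association regardless of affinity or the per-inhibitor cap, for trials
#' through the target year). Test negatives are sampled uniformly with all
#' evidence pairs, the exclusion pairs and both training sets excluded, which
#' guarantees the negative training and test sets are disjoint.
#'
#' @param evidence Evidence table from the filtered target map.
#' @param any_affinity_evidence Evidence table from the unfiltered target map
#'   (no affinity cutoff, no cap); used only for the exclusion rule.
#' @param split_so_far List with `positives_train` and `negatives_train` pair
#'   tables.
#' @param universe Candidate pair table for negative sampling.
#' @param config A [split_config()].
#' @return List with `positives_test` and `negatives_test` pair tables.
#' @export
build_test_sets <- function(evidence, any_affinity_evidence, split_so_far,
                            universe, config) {
  ev <- as.data.table(evidence)
  anyev <- as.data.table(any_affinity_evidence)

  qual <- if (config$test_phase_filter == "phase_iv_only") {
    ev[as.character(phase) == "IV"]
  } else ev
  first_year <- qual[, .(first = min(start_year)), by = .(pk, cancer)]
  pos <- first_year[first >= config$test_window[1] &
                      first <= config$test_window[2], .(pk, cancer)]

  seen_by_target <- unique(rbind(
    ev[start_year <= config$target_year, .(pk, cancer)],
    anyev[start_year <= config$target_year, .(pk, cancer)]
  ))
  pos <- pos[!pair_key(pk, cancer) %in%
               pair_key(seen_by_target$pk, seen_by_target$cancer)]
  setorderv(pos, c("pk", "cancer"))

  excluded <- rbind(
    unique(ev[, .(pk, cancer)]),
    unique(anyev[, .(pk, cancer)]),
    split_so_far$positives_train[, .(pk, cancer)],
    split_so_far$negatives_train[, .(pk, cancer)]
  )
  neg <- sample_negative_set(universe, excluded,
                             config$neg_ratio * nrow(pos),
                             seed = config$seed + 1L)
  list(positives_test = pos[], negatives_test = neg)
}

#' The de-novo prediction universe
#'
#' All kinase x cancer pairs except those with trial evidence in any phase.
#' Kinases absent from every activity record still appear paired with every
#' cancer: untargeted kinases are exactly the interesting candidates.
#'
#' @param all_pks,all_cancers Character vectors of identifiers.
#' @param evidence Evidence table; its pairs are removed from the product.
#' @return `data.table` with `pk`, `cancer`, sorted.
#' @export
build_prediction_universe <- function(all_pks, all_cancers, evidence) {
  grid <- data.table(pk = rep(sort(unique(all_pks)),
                              each = length(unique(all_cancers))),
                     cancer = rep(sort(unique(all_cancers)),
                                  times = length(unique(all_pks))))
  ev <- as.data.table(evidence)
  if (nrow(ev) > 0L) {
    grid <- grid[!pair_key(pk, cancer) %in% pair_key(ev$pk, ev$cancer)]
  }
  setorderv(grid, c("pk", "cancer"))
  grid[]
}

#' Build a complete labeled train/test split
#'
#' Driver combining [build_positive_train()], [sample_negative_set()] and
#' [build_test_sets()]. The candidate universe for negative sampling is the
#' full kinase x cancer grid over `all_pks` and `all_cancers` (callers
#' typically restrict these to identifiers whose concept tokens have
#' embeddings, since pairs without vectors cannot be featurized).
#'
#' @inheritParams build_test_sets
#' @param all_pks,all_cancers Identifier vectors spanning the candidate grid.
#' @return An object of class `kce_split`: list with `positives_train`,
#'   `negatives_train`, `positives_test`, `negatives_test`, `universe` and
#'   `config`.
#' @export
build_split <- function(evidence, any_affinity_evidence, all_pks, all_cancers,
                        config) {
  universe <- data.table(
    pk = rep(sort(unique(all_pks)), each = length(unique(all_cancers))),
    cancer = rep(sort(unique(all_cancers)), times = length(unique(all_pks)))
  )
  pos_train <- build_positive_train(evidence, config)
  ev <- as.data.table(evidence)
  anyev <- as.data.table(any_affinity_evidence)
  seen <- unique(rbind(ev[, .(pk, cancer)], anyev[, .(pk, cancer)]))
  neg_train <- sample_negative_set(universe, seen,
                                   config$neg_ratio * nrow(pos_train),
                                   seed = config$seed)
  test <- build_test_sets(evidence, any_affinity_evidence,
                          list(positives_train = pos_train,
                               negatives_train = neg_train),
                          universe, config)
  structure(list(positives_train = pos_train, negatives_train = neg_train,
                 positives_test = test$positives_test,
                 negatives_test = test$negatives_test,
                 universe = universe, config = config),
            class = "kce_split")
}

#' @export
print.kce_split <- function(x, ...) {
  cat(sprintf(paste0("kce_split (target year %d, window %d-%d, %s):\n",
                     "  train: %d positive / %d negative\n",
                     "  test:  %d positive / %d negative\n"),
              x$config$target_year, x$config$test_window[1],
              x$config$test_window[2], x$config$test_phase_filter,
              nrow(x$positives_train), nrow(x$negatives_train),
              nrow(x$positives_test), nrow(x$negatives_test)))
  invisible(x)
}

#' Write a split to disk
#'
#' Four TSV files (`pk`, `cancer`, `label`, `role`) plus a JSON manifest with
#' the configuration and counts.
#'
#' @param split A `kce_split`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sets <- list(positives_train = c(1L, "train"), negatives_train = c(0L, "train"),
               positives_test = c(1L, "test"), negatives_test = c(0L, "test"))
  for (nm in names(sets)) {
    tab <- copy(split[[nm]])
    tab[, label := as.integer(sets[[nm]][1])]
    tab[, role := sets[[nm]][2]]
    fwrite(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t")
  }
  manifest <- list(
    target_year = split$config$target_year,
    test_window = split$config$test_window,
    test_phase_filter = split$config$test_phase_filter,
    neg_ratio = split$config$neg_ratio,
    seed = split$config$seed,
    counts = lapply(split[names(sets)], nrow)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
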