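#' Configuration of the synthetic study generator
#'
#' The generator emulates the five pipeline inputs (article table, concept
#' annotations, MeSH hierarchy, kinase-activity table, clinical-trials table)
#' with a planted set of true kinase-cancer pairs. Each true pair receives
#' `docs_per_true_pair` abstracts mentioning both concepts (annotated spans)
#' together with a pair-specific cluster of context words and a handful of
#' shared treatment-relation words; background documents mix random
#' vocabulary with a single random concept mention, so every concept token
#' clears the frequency floor without creating spurious co-occurrence. Each
#' true pair is backed by one inhibitor with sub-threshold affinity for its
#' kinase and by clinical trials whose phase-IV start year is drawn from
#' `year_range`; decoy inhibitors (including `cap_exceeders` with
#' `n_pk + 2` sub-threshold targets, exercising the per-inhibitor cap) and
#' decoy phase I-II trials populate the negative space.
#'
#' @param n_pk,n_cancer Numbers of kinase and cancer concepts.
#' @param n_true_pairs Planted therapeutically-relevant pairs.
#' @param docs_per_true_pair Signal documents per true pair.
#' @param background_docs Background documents.
#' @param vocab_size Background vocabulary size.
#' @param context_words_per_pair Pair-specific context words.
#' @param doc_length Tokens per document (title + abstract).
#' @param pki_count Total inhibitors (must cover true pairs, cap exceeders
#'   and at least one decoy).
#' @param trials_per_true_pair Trials generated per true pair.
#' @param cap_exceeders Inhibitors given `n_pk + 2` sub-threshold targets.
#' @param year_range Integer vector `c(first, last)` for trial start years.
#' @param seed Integer seed; generation is byte-reproducible.
#' @return An object of class `kce_synth_config`.
#' @export
synth_config <- function(n_pk = 30L, n_cancer = 30L, n_true_pairs = 40L,
                         docs_per_true_pair = 60L, background_docs = 3000L,
                         vocab_size = 600L, context_words_per_pair = 6L,
                         doc_length = 30L, pki_count = 50L,
                         trials_per_true_pair = 3L, cap_exceeders = 2L,
                         year_range = c(2001L, 2020L), seed = 7L) {
  cfg <- list(
    n_pk = check_count(n_pk, "n_pk"),
    n_cancer = check_count(n_cancer, "n_cancer"),
    n_true_pairs = check_count(n_true_pairs, "n_true_pairs", min = 0L),
    docs_per_true_pair = check_count(docs_per_true_pair, "docs_per_true_pair", min = 0L),
    background_docs = check_count(background_docs, "background_docs", min = 0L),
    vocab_size = check_count(vocab_size, "vocab_size"),
    context_words_per_pair = check_count(context_words_per_pair, "context_words_per_pair", min = 0L),
    doc_length = check_count(doc_length, "doc_length", min = 10L),
    pki_count = check_count(pki_count, "pki_count"),
    trials_per_true_pair = check_count(trials_per_true_pair, "trials_per_true_pair"),
    cap_exceeders = check_count(cap_exceeders, "cap_exceeders", min = 0L),
    year_range = as.integer(year_range),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_true_pairs > cfg$n_pk * cfg$n_cancer) {
    kce_stop("n_true_pairs exceeds the number of possible pairs", "kce_config_error")
  }
  if (length(cfg$year_range) != 2L || cfg$year_range[1] > cfg$year_range[2]) {
    kce_stop("`year_range` must be c(first, last) with first <= last", "kce_config_error")
  }
  if (cfg$pki_count < cfg$n_true_pairs + cfg$cap_exceeders + 1L) {
    kce_stop("`pki_count` must cover true pairs, cap exceeders and a decoy",
             "kce_config_error")
  }
  structure(cfg, class = "kce_synth_config")
}

# identifier scheme shared by the generator and its token maps
synth_pk_symbols <- function(n) sprintf("PK%02d", seq_len(n))
synth_pk_gene_ids <- function(n) as.character(1000L + seq_len(n))
synth_cancer_ids <- function(n) sprintf("D1%05d", seq_len(n))

#' Concept token maps for synthetic identifiers
#'
#' @param config A [synth_config()].
#' @return List with `pk` (kinase symbol -> gene concept token) and `cancer`
#'   (MeSH id -> disease concept token) named character vectors.
#' @export
synth_token_maps <- function(config) {
  pk <- stats::setNames(paste0("ncbigene", synth_pk_gene_ids(config$n_pk)),
                        synth_pk_symbols(config$n_pk))
  cancer <- stats::setNames(tolower(paste0("mesh", synth_cancer_ids(config$n_cancer))),
                            synth_cancer_ids(config$n_cancer))
  list(pk = pk, cancer = cancer)
}

# a document as (title segments, abstract segments); a segment is a word
# vector, optionally annotated as one concept span
synth_doc <- function(pmid, year, mesh_id, title_segs, abstract_segs) {
  render <- function(segs) {
    vapply(segs, function(s) paste(s$words, collapse = " "), character(1))
  }
  title <- paste(render(title_segs), collapse = " ")
  abstract <- paste(render(abstract_segs), collapse = " ")
  # offsets into title + " " + abstract
  anns <- list()
  pos <- 0L
  for (part in list(title_segs, abstract_segs)) {
    for (s in part) {
      seg_text <- paste(s$words, collapse = " ")
      if (!is.null(s$category)) {
        anns[[length(anns) + 1L]] <- data.table(
          pmid = pmid, start = pos, end = pos + nchar(seg_text),
          category = s$category, concept_id = s$concept_id)
      }
      pos <- pos + nchar(seg_text) + 1L # the joining space
    }
  }
  list(
    article = data.table(pmid = pmid, year = year, mesh_ids = list(mesh_id),
                         keywords = list(character()), title = title,
                         abstract = abstract),
    anns = rbindlist(anns)
  )
}

seg <- function(words, category = NULL, concept_id = NULL) {
  list(words = words, category = category, concept_id = concept_id)
}

pk_surface <- function(i) c("kinase", sprintf("alpha%02d", i))
cancer_surface <- function(j) c(sprintf("organ%02d", j), "carcinoma")

#' Generate the synthetic article and annotation tables
#'
#' @param config A [synth_config()].
#' @return List with `articles` (article record table), `annotations`
#'   (annotation table) and `truth` (list with `true_pairs` pair table,
#'   `pair_year` named integer vector keyed by `pk\\x1fcancer`, and the token
#'   maps).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "kce_synth_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  pks <- synth_pk_symbols(config$n_pk)
  gene_ids <- synth_pk_gene_ids(config$n_pk)
  cancers <- synth_cancer_ids(config$n_cancer)
  years <- seq.int(config$year_range[1], config$year_range[2])
  bg_words <- sprintf("w%04d", seq_len(config$vocab_size))
  # the relational signal: therapeutically-relevant kinases are written about
  # with inhibition vocabulary, their cancers with treatment-response
  # vocabulary; the two one-sided word sets are shared across all true pairs,
  # so positive difference vectors share a direction (relational structure),
  # while the per-pair context words add pair-specific proximity
  pk_side_words <- c("inhibition", "inhibitor", "blockade", "phosphorylation",
                     "selectivity", "potency")
  cancer_side_words <- c("remission", "regression", "survival", "shrinkage",
                         "durable", "relapse")
  # every concept has its own signature vocabulary: background mentions are
  # flanked by the concept's own signature (genes and diseases each have a
  # literature of their own, keeping unrelated vectors apart), while the
  # relation documents of a true pair flank BOTH mentions with the union of
  # the two signatures — the two concepts of a true pair then see
  # near-identical context distributions even when one of them participates
  # in several pairs, whereas mismatched concepts share no signature words
  sig_n <- max(2L, config$context_words_per_pair %/% 2L)
  pk_sig <- lapply(seq_len(config$n_pk),
                   function(i) paste0("gsig", i, letters[seq_len(sig_n)]))
  ca_sig <- lapply(seq_len(config$n_cancer),
                   function(j) paste0("csig", j, letters[seq_len(sig_n)]))

  # planted pairs are sampled with a per-concept multiplicity cap (a kinase
  # treats at most a couple of cancers and vice versa, as in curated
  # drug-target evidence); unbounded multiplicity would smear a concept's
  # vector across many pair clusters
  cap <- max(2L, ceiling(config$n_true_pairs /
                           min(config$n_pk, config$n_cancer)))
  grid <- data.table(pk = rep(pks, each = config$n_cancer),
                     cancer = rep(cancers, times = config$n_pk))
  grid <- grid[sample(.N)]
  used_pk <- stats::setNames(integer(config$n_pk), pks)
  used_ca <- stats::setNames(integer(config$n_cancer), cancers)
  take <- logical(nrow(grid))
  n_taken <- 0L
  for (i in seq_len(nrow(grid))) {
    if (n_taken >= config$n_true_pairs) break
    p <- grid$pk[i]; ca <- grid$cancer[i]
    if (used_pk[p] >= cap || used_ca[ca] >= cap) next
    take[i] <- TRUE
    used_pk[p] <- used_pk[p] + 1L
    used_ca[ca] <- used_ca[ca] + 1L
    n_taken <- n_taken + 1L
  }
  if (n_taken < config$n_true_pairs) {
    kce_stop("could not place all true pairs under the multiplicity cap",
             "kce_config_error")
  }
  true_pairs <- grid[take]
  setorderv(true_pairs, c("pk", "cancer"))
  true_keys <- pair_key(true_pairs$pk, true_pairs$cancer)
  pair_year <- stats::setNames(
    sample(years, config$n_true_pairs, replace = TRUE), true_keys)

  docs <- list()
  next_pmid <- 1L
  pk_idx <- match(true_pairs$pk, pks)
  ca_idx <- match(true_pairs$cancer, cancers)
  cw <- 2L * sig_n
  for (t in seq_len(max(config$n_true_pairs, 0L))) {
    ctx <- c(pk_sig[[pk_idx[t]]], ca_sig[[ca_idx[t]]])
    for (d in seq_len(config$docs_per_true_pair)) {
      pseg <- seg(pk_surface(pk_idx[t]), "gene", gene_ids[pk_idx[t]])
      cseg <- seg(cancer_surface(ca_idx[t]), "disease", true_pairs$cancer[t])
      filler_n <- max(config$doc_length - (10L + 2L * cw + 4L), 4L)
      f1 <- filler_n %/% 2L
      # both mentions flanked by the union of the two signatures; one
      # inhibition word near the kinase and one treatment-response word near
      # the cancer add a light relational flavour
      abstract_segs <- list(
        seg(c(sample(cancer_side_words, 1L), sample(ctx, cw %/% 2L))),
        cseg,
        seg(sample(ctx)),
        seg(sample(bg_words, f1, replace = TRUE)),
        seg(c(sample(pk_side_words, 1L), sample(ctx, cw %/% 2L))),
        pseg,
        seg(sample(ctx)),
        seg(sample(bg_words, filler_n - f1, replace = TRUE))
      )
      # occasional decoy mention of an unrelated concept
      if (runif(1) < 0.15) {
        if (runif(1) < 0.5) {
          j <- sample.int(config$n_pk, 1L)
          abstract_segs <- c(abstract_segs,
                             list(seg(pk_surface(j), "gene", gene_ids[j])))
        } else {
          j <- sample.int(config$n_cancer, 1L)
          abstract_segs <- c(abstract_segs,
                             list(seg(cancer_surface(j), "disease", cancers[j])))
        }
      }
      docs[[next_pmid]] <- synth_doc(
        pmid = sprintf("S%06d", next_pmid),
        year = sample(years, 1L),
        mesh_id = true_pairs$cancer[t],
        title_segs = list(seg(c("Trial", "of")), pseg, seg("in"), cseg),
        abstract_segs = abstract_segs
      )
      next_pmid <- next_pmid + 1L
    }
  }

  # background-mention allocation: concepts inside true pairs are written
  # about mostly in their relation documents (heavily studied), so they get
  # just enough background mentions to clear the frequency floor; concepts
  # outside any true pair receive the rest, cycling, which trains their
  # signature-flavoured vectors well and keeps them apart from each other
  n_concepts <- config$n_pk + config$n_cancer
  concept_in_truth <- c(pks %in% true_pairs$pk, cancers %in% true_pairs$cancer)
  bg_order <- rep(which(concept_in_truth), times = 8L)
  rest <- which(!concept_in_truth)
  if (length(rest) == 0L) rest <- seq_len(n_concepts)
  n_rest <- max(config$background_docs - length(bg_order), 0L)
  bg_order <- c(bg_order, rep(rest, length.out = n_rest))
  bg_order <- bg_order[seq_len(min(length(bg_order), config$background_docs))]
  for (b in seq_along(bg_order)) {
    ci <- bg_order[b]
    if (ci <= config$n_pk) {
      cseg <- seg(pk_surface(ci), "gene", gene_ids[ci])
      sig <- pk_sig[[ci]]
      mesh_id <- "D009369"
    } else {
      j <- ci - config$n_pk
      cseg <- seg(cancer_surface(j), "disease", cancers[j])
      sig <- ca_sig[[j]]
      mesh_id <- cancers[j]
    }
    filler_n <- max(config$doc_length - 14L, 2L)
    docs[[next_pmid]] <- synth_doc(
      pmid = sprintf("S%06d", next_pmid),
      year = sample(years, 1L),
      mesh_id = mesh_id,
      title_segs = list(seg(c("Report", "on")), cseg),
      abstract_segs = list(
        seg(sample(sig)),
        cseg,
        seg(sample(sig)),
        seg(sample(bg_words, filler_n, replace = TRUE))
      )
    )
    next_pmid <- next_pmid + 1L
  }

  if (length(docs) == 0L) {
    return(list(articles = empty_articles(),
                annotations = data.table(pmid = character(), start = integer(),
                                         end = integer(), category = character(),
                                         concept_id = character()),
                truth = list(true_pairs = true_pairs, pair_year = pair_year,
                             token_maps = synth_token_maps(config))))
  }
  list(
    articles = rbindlist(lapply(docs, `[[`, "article")),
    annotations = rbindlist(lapply(docs, `[[`, "anns")),
    truth = list(true_pairs = true_pairs, pair_year = pair_year,
                 token_maps = synth_token_maps(config))
  )
}

#' The synthetic MeSH hierarchy
#'
#' Two roots — D009369 (neoplasms) with every synthetic cancer descriptor as
#' a child, and D011494 (protein kinases) — written in the JSON-lines dialect
#' of [read_mesh_hierarchy()] or returned as a `kce_mesh` object.
#'
#' @param config A [synth_config()].
#' @param path Optional output path; when given, the JSON-lines file is
#'   written and the path returned invisibly.
#' @return A `kce_mesh` object (or `path`).
#' @export
generate_mesh_hierarchy <- function(config, path = NULL) {
  cancers <- synth_cancer_ids(config$n_cancer)
  nodes <- c(
    list(
      D009369 = list(label = "Neoplasms", synonyms = c("Tumors", "Cancer"),
                     parents = character()),
      D011494 = list(label = "Protein Kinases",
                     synonyms = "Protein Phosphotransferases",
                     parents = character())
    ),
    stats::setNames(lapply(seq_along(cancers), function(j) {
      list(label = sprintf("Organ %02d carcinoma", j),
           synonyms = sprintf("organ%02d cancer", j),
           parents = "D009369")
    }), cancers)
  )
  hier <- structure(nodes, class = "kce_mesh")
  if (is.null(path)) return(hier)
  lines <- vapply(names(nodes), function(id) {
    jsonlite::toJSON(c(list(id = id), nodes[[id]]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the synthetic activity and trial tables
#'
#' @param config A [synth_config()].
#' @param truth Truth list from [generate_corpus()].
#' @return List with `activities` and `trials` tables in the dialects of
#'   [read_activities()] and [parse_trials()].
#' @export
generate_catalog_tables <- function(config, truth) {
  stopifnot(inherits(config, "kce_synth_config"))
  withr::with_seed(config$seed + 1L, generate_catalog_impl(config, truth))
}

generate_catalog_impl <- function(config, truth) {
  pks <- synth_pk_symbols(config$n_pk)
  cancers <- synth_cancer_ids(config$n_cancer)
  true_pairs <- truth$true_pairs
  true_keys <- pair_key(true_pairs$pk, true_pairs$cancer)
  years <- seq.int(config$year_range[1], config$year_range[2])

  acts <- list()
  trials <- list()
  nct <- 0L
  new_nct <- function() {
    nct <<- nct + 1L
    sprintf("NCT%08d", nct)
  }
  phase_label <- function(ph) {
    switch(ph,
           I = sample(c("Phase 1", "Phase I", "Early Phase 1"), 1L),
           II = sample(c("Phase 2", "Phase II", "Phase 1/Phase 2"), 1L),
           III = sample(c("Phase 3", "Phase III", "Phase 2/Phase 3"), 1L),
           IV = sample(c("Phase 4", "Phase IV"), 1L))
  }

  # one inhibitor per true pair, sub-threshold for the pair's kinase
  for (t in seq_len(nrow(true_pairs))) {
    pki <- sprintf("PKI%03d", t)
    acts[[length(acts) + 1L]] <- data.table(
      pki = pki, pk = true_pairs$pk[t],
      affinity_um = round(runif(1, 0.001, 0.029), 4), pmid = "")
    # an above-threshold record now and then, dropped by the affinity filter
    if (runif(1) < 0.3) {
      acts[[length(acts) + 1L]] <- data.table(
        pki = pki, pk = sample(pks, 1L),
        affinity_um = round(runif(1, 0.05, 2), 4), pmid = "")
    }
    y0 <- truth$pair_year[true_keys[t]]
    trials[[length(trials) + 1L]] <- data.table(
      nct_id = new_nct(), pki = pki, cancer_mesh = true_pairs$cancer[t],
      phase = phase_label("IV"), start_year = y0,
      completion_year = min(y0 + 2L, config$year_range[2]))
    for (e in seq_len(config$trials_per_true_pair - 1L)) {
      ph <- sample(c("I", "II", "III"), 1L)
      ys <- min(y0 + sample(0:1, 1L), config$year_range[2])
      trials[[length(trials) + 1L]] <- data.table(
        nct_id = new_nct(), pki = pki, cancer_mesh = true_pairs$cancer[t],
        phase = phase_label(ph), start_year = ys,
        completion_year = min(ys + 1L, config$year_range[2]))
    }
  }

  # cap exceeders: n_pk + 2 sub-threshold targets each
  cap_pkis <- character()
  for (i in seq_len(config$cap_exceeders)) {
    pki <- sprintf("PKIX%02d", i)
    cap_pkis <- c(cap_pkis, pki)
    tgt <- sample(pks, min(5L + 2L, config$n_pk)) # catalog default cap is 5
    acts[[length(acts) + 1L]] <- data.table(
      pki = pki, pk = tgt,
      affinity_um = round(runif(length(tgt), 0.001, 0.029), 4), pmid = "")
  }

  # plain decoys: one or two targets across the affinity range
  n_decoy <- config$pki_count - nrow(true_pairs) - config$cap_exceeders
  decoy_pkis <- sprintf("PKID%02d", seq_len(n_decoy))
  for (pki in decoy_pkis) {
    tgt <- sample(pks, sample(1:2, 1L))
    acts[[length(acts) + 1L]] <- data.table(
      pki = pki, pk = tgt,
      affinity_um = round(runif(length(tgt), 0.001, 0.1), 4), pmid = "")
  }

  # decoy trials: phases I-II only, never hitting a true pair
  act_tab <- rbindlist(acts)
  for (dpki in c(cap_pkis, decoy_pkis)) {
    tgts <- act_tab[pki == dpki, pk]
    for (r in seq_len(2L)) {
      ca <- NULL
      for (attempt in seq_len(50L)) {
        cand <- sample(cancers, 1L)
        if (!any(pair_key(tgts, cand) %in% true_keys)) {
          ca <- cand
          break
        }
      }
      if (is.null(ca)) next
      ys <- sample(years, 1L)
      trials[[length(trials) + 1L]] <- data.table(
        nct_id = new_nct(), pki = dpki, cancer_mesh = ca,
        phase = phase_label(sample(c("I", "II"), 1L)), start_year = ys,
        completion_year = min(ys + 1L, config$year_range[2]))
    }
  }

  list(activities = act_tab, trials = rbindlist(trials))
}

#' Write a complete synthetic input directory
#'
#' Writes `articles.tsv`, `annotations.tsv`, `mesh.jsonl`, `activities.tsv`,
#' `trials.tsv` and a `truth.json` manifest (the planted pairs, their
#' phase-IV years and the token maps) in the dialects the corresponding
#' readers consume.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
end_to_end_fixture <- function(config = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corp <- generate_corpus(config)
  cat_tabs <- generate_catalog_tables(config, corp$truth)

  art <- copy(corp$articles)
  art[, mesh_ids := vapply(mesh_ids, paste, character(1), collapse = ";")]
  art[, keywords := vapply(keywords, paste, character(1), collapse = ";")]
  fwrite(art, file.path(dir, "articles.tsv"), sep = "\t", quote = FALSE)
  fwrite(corp$annotations, file.path(dir, "annotations.tsv"), sep = "\t",
         quote = FALSE)
  generate_mesh_hierarchy(config, file.path(dir, "mesh.jsonl"))
  fwrite(cat_tabs$activities, file.path(dir, "activities.tsv"), sep = "\t",
         quote = FALSE)
  fwrite(cat_tabs$trials, file.path(dir, "trials.tsv"), sep = "\t",
         quote = FALSE)
  truth <- corp$truth
  jsonlite::write_json(
    list(true_pairs = truth$true_pairs,
         pair_year = as.list(stats::setNames(
           unname(truth$pair_year),
           sub("\x1f", "|", names(truth$pair_year), fixed = TRUE))),
         pk_token_map = as.list(truth$token_maps$pk),
         cancer_token_map = as.list(truth$token_maps$cancer)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Run the full pipeline on synthetic inputs
#'
#' Drives every stage — corpus preparation, embedding, catalog, historical
#' split, difference-vector random forest, evaluation — on a generated
#' synthetic study and returns the held-out evaluation together with all
#' intermediate objects. The target year defaults to the median phase-IV
#' year of the planted pairs, so roughly half of them train and half are
#' held out as future trials; the test window runs from the year after the
#' target year to the end of the year range.
#'
#' @param config A [synth_config()].
#' @param target_year Optional target year override.
#' @param embed_config An [embedding_config()]; defaults to the standard
#'   hyperparameters with the generator seed.
#' @param space A [search_space()]; the default uses 20 search iterations,
#'   sized to the synthetic corpus.
#' @param test_phase_filter Passed to [split_config()].
#' @return List with `evaluation` (a `kce_evaluation` on the held-out test
#'   set), `split`, `model`, `embedding`, `corpus`, `evidence`, `truth`,
#'   `test_scores`, `test_labels` and `config`.
#' @export
run_synthetic_pipeline <- function(config = synth_config(),
                                   target_year = NULL,
                                   embed_config = embedding_config(seed = config$seed),
                                   space = search_space(iterations = 20L,
                                                        seed = config$seed),
                                   test_phase_filter = "all_phases") {
  corp <- generate_corpus(config)
  cat_tabs <- generate_catalog_tables(config, corp$truth)
  hier <- generate_mesh_hierarchy(config)
  maps <- corp$truth$token_maps

  corpus <- prep_corpus(corp$articles, corp$annotations, hier,
                        search_ids = c("D009369", "D011494"))
  emb <- train_skipgram(corpus, embed_config)

  target_map <- filter_activities(cat_tabs$activities, catalog_config())
  any_map <- filter_activities(cat_tabs$activities,
                               catalog_config(affinity_max_um = Inf,
                                              n_pk = config$n_pk))
  trials <- parse_trials(cat_tabs$trials,
                         cancer_lexicon = synth_cancer_ids(config$n_cancer),
                         pki_set = unique(cat_tabs$activities$pki))
  evidence <- derive_pair_evidence(trials, target_map)
  any_evidence <- derive_pair_evidence(trials, any_map)

  if (is.null(target_year)) {
    iv_years <- evidence[as.character(phase) == "IV", start_year]
    target_year <- as.integer(stats::median(iv_years))
  }
  vocab <- rownames(emb$input)
  all_pks <- names(maps$pk)[maps$pk %in% vocab]
  all_cancers <- names(maps$cancer)[maps$cancer %in% vocab]
  cfg <- split_config(target_year = target_year,
                      test_window = c(target_year + 1L, config$year_range[2]),
                      test_phase_filter = test_phase_filter,
                      seed = config$seed)
  split <- build_split(evidence, any_evidence, all_pks, all_cancers, cfg)

  label_pairs <- function(tab, lab) {
    tab <- copy(tab)
    tab[, label := lab]
    tab
  }
  train_tab <- rbind(label_pairs(split$positives_train, 1L),
                     label_pairs(split$negatives_train, 0L))
  test_tab <- rbind(label_pairs(split$positives_test, 1L),
                    label_pairs(split$negatives_test, 0L))
  train_rows <- build_difference_features(train_tab, emb, maps$pk, maps$cancer)
  test_rows <- build_difference_features(test_tab, emb, maps$pk, maps$cancer)

  model <- train_classifier(train_rows, space)
  scores <- score_pairs(model, test_rows)
  ev <- evaluate(scores, test_rows$pairs$label)

  list(evaluation = ev, split = split, model = model, embedding = emb,
       corpus = corpus, evidence = evidence, any_evidence = any_evidence,
       truth = corp$truth, test_scores = scores,
       test_labels = test_rows$pairs$label, config = config,
       target_year = target_year)
}

#' Label-permutation control for a held-out evaluation
#'
#' Re-evaluates the same scores after randomly permuting which test pairs are
#' labeled positive, averaged over `n_perm` permutations. With no association
#' between scores and labels the expected AUROC is 0.5; the average over
#' permutations concentrates tightly around it.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Mean AUROC over the permutations.
#' @export
permutation_auroc <- function(scores, labels, n_perm = 20L, seed = 1L) {
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_perm), function(i) {
      evaluate(scores, sample(labels))$auroc
    }, numeric(1)))
  })
}
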