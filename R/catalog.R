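#' Catalog configuration: affinity cutoff and targets-per-inhibitor cap
#'
#' A kinase counts as a target of an inhibitor only when some experimental
#' activity (Ki, IC50, ...) is below `affinity_max_um` micromolar — 0.03 uM is
#' the cutoff under which a drug plausibly acts through the kinase — and each
#' inhibitor keeps at most `n_pk` targets, the ones with the lowest
#' (strongest-binding) affinities.
#'
#' @param affinity_max_um Positive affinity threshold in micromolar.
#' @param n_pk Maximum kinases retained per inhibitor.
#' @return An object of class `kce_catalog_config`.
#' @export
catalog_config <- function(affinity_max_um = 0.03, n_pk = 5L) {
  if (!is.numeric(affinity_max_um) || length(affinity_max_um) != 1L ||
      affinity_max_um <= 0) {
    kce_stop("`affinity_max_um` must be a positive number", "kce_config_error")
  }
  structure(list(affinity_max_um = affinity_max_um,
                 n_pk = check_count(n_pk, "n_pk")),
            class = "kce_catalog_config")
}

#' Read a kinase-activity table
#'
#' TSV with header and columns `pki`, `pk`, `affinity_um`, `pmid` (the PMID
#' may be empty).
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return `data.table` with those four columns, affinity numeric.
#' @export
read_activities <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE,
               colClasses = list(character = c("pki", "pk", "pmid"),
                                 numeric = "affinity_um"),
               quote = "", encoding = "UTF-8")
  need <- c("pki", "pk", "affinity_um", "pmid")
  if (!all(need %in% names(tab))) {
    kce_stop(sprintf("activity table is missing column(s): %s",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "kce_parse_error")
  }
  tab[, need, with = FALSE]
}

#' Build the inhibitor-to-kinase target map from activity records
#'
#' For each (inhibitor, kinase) pair the minimum affinity across records is
#' kept (the most potent measurement); pairs at or above the affinity cutoff
#' are dropped; each inhibitor then retains its `n_pk` strongest-binding
#' kinases, ordered by ascending affinity with ties broken by kinase symbol.
#'
#' @param records Activity table (`pki`, `pk`, `affinity_um`, optional `pmid`).
#' @param config A [catalog_config()].
#' @return Named list: inhibitor id -> character vector of kinase symbols in
#'   deterministic order. The per-pair minimum affinities are attached as the
#'   `affinities` attribute (a `data.table`).
#' @export
filter_activities <- function(records, config = catalog_config()) {
  records <- as.data.table(records)
  if (nrow(records) == 0L) {
    out <- structure(list(), names = character())
    attr(out, "affinities") <- data.table(pki = character(), pk = character(),
                                          affinity_um = numeric())
    return(out)
  }
  if (any(!is.finite(records$affinity_um) | records$affinity_um <= 0)) {
    i <- which(!is.finite(records$affinity_um) | records$affinity_um <= 0)[1L]
    kce_stop(sprintf("activity record %d (%s/%s): non-positive affinity %s",
                     i, records$pki[i], records$pk[i],
                     deparse(records$affinity_um[i])),
             "kce_validation_error")
  }
  best <- records[, .(affinity_um = min(affinity_um)), by = .(pki, pk)]
  best <- best[affinity_um < config$affinity_max_um]
  setorderv(best, c("pki", "affinity_um", "pk"))
  best <- best[, head(.SD, config$n_pk), by = pki]
  out <- split(best$pk, best$pki)
  # split() sorts groups; keep that order but drop factor baggage
  out <- lapply(out, as.character)
  attr(out, "affinities") <- best
  out
}

#' Read and filter a clinical-trials table
#'
#' TSV with header and columns `nct_id`, `pki`, `cancer_mesh`, `phase`,
#' `start_year`, `completion_year`. Rows are kept when the condition id is in
#' the cancer lexicon and the drug is in the inhibitor set; phases are
#' normalized to I/II/III/IV (combined labels such as "Phase 1/Phase 2"
#' normalize to the higher phase). Rows that fail a filter or do not parse
#' are dropped and counted in the attached skip report, never fatal.
#'
#' @param table Path to the TSV, or an already-read `data.frame`.
#' @param cancer_lexicon Character vector of cancer MeSH descriptor ids.
#' @param pki_set Character vector of inhibitor identifiers.
#' @return `data.table` of trial records (`nct_id`, `pki`, `cancer`, `phase`
#'   as factor I<II<III<IV, `start_year`, `completion_year`), with a
#'   `skip_report` attribute (named integer vector of drop reasons).
#' @export
parse_trials <- function(table, cancer_lexicon, pki_set) {
  tab <- if (is.character(table)) {
    fread(table, sep = "\t", header = TRUE, colClasses = "character",
          quote = "", na.strings = NULL, encoding = "UTF-8")
  } else {
    as.data.table(lapply(table, as.character))
  }
  need <- c("nct_id", "pki", "cancer_mesh", "phase", "start_year",
            "completion_year")
  if (!all(need %in% names(tab))) {
    kce_stop(sprintf("trials table is missing column(s): %s",
                     paste(setdiff(need, names(tab)), collapse = ", ")),
             "kce_parse_error")
  }
  skips <- c(not_cancer = 0L, unknown_pki = 0L, bad_phase = 0L, bad_year = 0L)
  keep <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!(tab$cancer_mesh[i] %in% cancer_lexicon)) {
      skips["not_cancer"] <- skips["not_cancer"] + 1L
      next
    }
    if (!(tab$pki[i] %in% pki_set)) {
      skips["unknown_pki"] <- skips["unknown_pki"] + 1L
      next
    }
    ph <- normalize_phase(tab$phase[i])
    if (is.na(ph)) {
      skips["bad_phase"] <- skips["bad_phase"] + 1L
      next
    }
    sy <- suppressWarnings(as.integer(tab$start_year[i]))
    cy <- suppressWarnings(as.integer(tab$completion_year[i]))
    if (is.na(sy)) {
      skips["bad_year"] <- skips["bad_year"] + 1L
      next
    }
    keep[[i]] <- data.table(nct_id = tab$nct_id[i], pki = tab$pki[i],
                            cancer = tab$cancer_mesh[i], phase = ph,
                            start_year = sy, completion_year = cy)
  }
  out <- rbindlist(keep)
  if (nrow(out) == 0L) {
    out <- data.table(nct_id = character(), pki = character(),
                      cancer = character(), phase = character(),
                      start_year = integer(), completion_year = integer())
  }
  out[, phase := factor(phase, levels = c("I", "II", "III", "IV"),
                        ordered = TRUE)]
  attr(out, "skip_report") <- skips
  out[]
}

#' Normalize a free-text trial phase label to I/II/III/IV
#'
#' Accepts roman and arabic forms ("Phase 3", "Phase III", "3", "IV");
#' combined labels ("Phase 1/Phase 2", "Phase II/III") map to the higher
#' phase. Returns `NA` for labels carrying no phase (e.g. "N/A",
#' "Early Phase 1" maps to I).
#'
#' @param x Character scalar.
#' @return `"I"`, `"II"`, `"III"`, `"IV"` or `NA_character_`.
#' @export
normalize_phase <- function(x) {
  u <- toupper(x)
  hits <- integer()
  if (grepl("(^|[^I])IV([^A-Z]|$)", u) || grepl("4", u)) hits <- c(hits, 4L)
  if (grepl("III", u) || grepl("3", u)) hits <- c(hits, 3L)
  if (grepl("(^|[^I])II([^I]|$)", u) || grepl("2", u)) hits <- c(hits, 2L)
  if (grepl("(^|[^I])I([^I]|$)", u) || grepl("1", u)) hits <- c(hits, 1L)
  if (length(hits) == 0L) return(NA_character_)
  c("I", "II", "III", "IV")[max(hits)]
}

#' Join trials with the target map into kinase-cancer evidence pairs
#'
#' Every trial of an inhibitor against a cancer contributes one evidence
#' record (phase, start year, NCT id, inhibitor) to the pair (kinase, cancer)
#' for each kinase the inhibitor targets; evidence for the same pair is
#' merged across trials. Trials whose inhibitor has no targets are ignored
#' and counted in the skip report.
#'
#' @param trials Trial table from [parse_trials()].
#' @param target_map Named list from [filter_activities()].
#' @return `data.table` with one row per evidence record: `pk`, `cancer`,
#'   `phase`, `start_year`, `nct_id`, `pki`; `skip_report` attribute counts
#'   trials without targets.
#' @export
derive_pair_evidence <- function(trials, target_map) {
  trials <- as.data.table(trials)
  skipped <- 0L
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    pks <- target_map[[trials$pki[i]]]
    if (is.null(pks) || length(pks) == 0L) {
      skipped <- skipped + 1L
      next
    }
    rows[[i]] <- data.table(pk = pks, cancer = trials$cancer[i],
                            phase = as.character(trials$phase[i]),
                            start_year = trials$start_year[i],
                            nct_id = trials$nct_id[i], pki = trials$pki[i])
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table(pk = character(), cancer = character(),
                      phase = character(), start_year = integer(),
                      nct_id = character(), pki = character())
  }
  out <- unique(out)
  setorderv(out, c("pk", "cancer", "start_year", "nct_id"))
  attr(out, "skip_report") <- c(no_targets = skipped)
  out[]
}

#' Summary statistics of a filtered target map
#'
#' The worked-example statistics over inhibitor-kinase pairs: total pair
#' count, number of distinct inhibitors and kinases, and the mean / median /
#' min / max of kinases per inhibitor and inhibitors per kinase.
#'
#' @param target_map Named list from [filter_activities()].
#' @return Named list of the statistics.
#' @export
summarize_target_map <- function(target_map) {
  pairs <- data.table(pki = rep(names(target_map), lengths(target_map)),
                      pk = unlist(target_map, use.names = FALSE))
  per_pki <- if (nrow(pairs)) pairs[, .N, by = pki]$N else integer()
  per_pk <- if (nrow(pairs)) pairs[, .N, by = pk]$N else integer()
  list(
    n_pairs = nrow(pairs),
    n_pki = length(per_pki),
    n_pk = length(per_pk),
    pks_per_pki = c(mean = mean(per_pki), median = stats::median(per_pki),
                    min = suppressWarnings(as.numeric(min(per_pki))),
                    max = suppressWarnings(as.numeric(max(per_pki)))),
    pkis_per_pk = c(mean = mean(per_pk), median = stats::median(per_pk),
                    min = suppressWarnings(as.numeric(min(per_pk))),
                    max = suppressWarnings(as.numeric(max(per_pk))))
  )
}

#' Per-phase counts of a trial table
#'
#' @param trials Trial table from [parse_trials()].
#' @return Named integer vector with entries `I`, `II`, `III`, `IV` and
#'   `total`.
#' @export
summarize_trials <- function(trials) {
  counts <- table(factor(as.character(trials$phase),
                         levels = c("I", "II", "III", "IV")))
  out <- as.integer(counts)
  names(out) <- names(counts)
  c(out, total = sum(out))
}
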