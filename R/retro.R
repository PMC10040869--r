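# Retrospective hold-out validation: withhold the query target's known
# actives from training, train on the remaining (homolog-derived) chemistry,
# then check that the models score the withheld actives above a general
# screening library.

#' Withhold the query target's actives from a labeled set
#'
#' A compound is withheld when it is labeled active and its active evidence
#' (per-target medians passing the cutoff) derives solely from the query
#' target. Compounds that are also active on at least one other expanded
#' target remain in training: removing them would discard legitimate homolog
#' evidence.
#'
#' @param labeled an `lvs_labeled` set from [label_compounds()].
#' @param query_uniprot accession of the query target.
#' @return list with `training` (labeled set minus withheld), `withheld`
#'   (the held-out actives), and `evaluable` (FALSE when the query has no
#'   recorded actives, with a warning).
#' @export
withhold_query_actives <- function(labeled, query_uniprot) {
  per_target <- attr(labeled, "per_target")
  if (is.null(per_target)) {
    stop("labeled set lacks per-target evidence (rebuild with label_compounds())",
         call. = FALSE)
  }
  active_targets <- per_target[per_target$passes, , drop = FALSE] |>
    dplyr::group_by(.data$inchikey) |>
    dplyr::summarise(targets = list(unique(.data$target_uniprot)), .groups = "drop")
  solely_query <- vapply(active_targets$targets, function(t)
    identical(t, query_uniprot), TRUE)
  withheld_keys <- active_targets$inchikey[solely_query]
  withheld_keys <- intersect(withheld_keys, labeled$inchikey[labeled$label == "active"])

  withheld <- labeled[labeled$inchikey %in% withheld_keys, , drop = FALSE]
  training <- labeled[!labeled$inchikey %in% withheld_keys, , drop = FALSE]
  attr(training, "per_target") <- per_target
  attr(training, "value_type") <- attr(labeled, "value_type")
  evaluable <- nrow(withheld) > 0
  if (!evaluable) {
    warning("query target has no solely-attributed actives; retrospective ",
            "validation is not evaluable", call. = FALSE)
  }
  list(training = training, withheld = withheld, evaluable = evaluable)
}

#' Compare withheld-active scores with library scores
#'
#' Two-sided Welch (unequal-variance) comparison of means by default; a
#' rank-based Wilcoxon alternative is available. Significance stars follow the
#' conventional thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param withheld_scores,library_scores numeric score vectors.
#' @param model label carried into the result row.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return one-row tibble: means, SEMs, test statistic, p-value, stars,
#'   direction, and an `evaluable` flag (FALSE when either vector has fewer
#'   than 2 values, in which case the p-value is `NA`).
#' @export
compare_scores <- function(withheld_scores, library_scores, model = "model",
                           test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(length(withheld_scores) > 0, length(library_scores) > 0)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  evaluable <- length(withheld_scores) > 1 && length(library_scores) > 1
  if (evaluable) {
    ht <- if (test == "welch") {
      stats::t.test(withheld_scores, library_scores, var.equal = FALSE)
    } else {
      suppressWarnings(stats::wilcox.test(withheld_scores, library_scores))
    }
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    warning("score vector of length 1: p-value undefined", call. = FALSE)
    stat <- NA_real_; p <- NA_real_
  }
  stars <- if (is.na(p)) "ns" else if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  tibble::tibble(
    model = model,
    n_actives = length(withheld_scores),
    n_library = length(library_scores),
    mean_score_actives = mean(withheld_scores),
    mean_score_library = mean(library_scores),
    sem_actives = sem(withheld_scores),
    sem_library = sem(library_scores),
    test = test,
    test_statistic = stat,
    p_value = p,
    significance = stars,
    direction = ifelse(mean(withheld_scores) > mean(library_scores),
                       "actives_higher", "library_higher"),
    evaluable = evaluable
  )
}

#' Run the full retrospective validation protocol
#'
#' Expansion, curation and labeling over the fixture corpus; the query's
#' solely-attributed actives are withheld; training is balanced by
#' undersampling; RF and MLP classifiers are trained with grid search; the
#' withheld actives and the screening library are scored and compared.
#'
#' @param homology fixture homology table (path or data frame).
#' @param bioactivity bioactivity records (path or data frame).
#' @param library an `lvs_library` (or path to one readable by
#'   [read_library()]).
#' @param query_uniprot accession of the query target.
#' @param identity_cutoff homology identity cutoff (default 40).
#' @param fp_spec fingerprint spec for the whole run.
#' @param config a [training_config()].
#' @param test significance test passed to [compare_scores()].
#' @return list: `results` (one row per model), `models`, `scores`
#'   (withheld + library per model), `training`, `withheld`, `labeled`,
#'   `expansion`.
#' @export
run_retrospective <- function(homology, bioactivity, library, query_uniprot,
                              identity_cutoff = 40,
                              fp_spec = fingerprint_spec(),
                              config = training_config(),
                              test = "welch") {
  query <- target_query(query_uniprot)
  backend <- homology_backend_fixture(homology)
  hits <- search_homologs(backend, query)
  expansion <- filter_homologs(hits, identity_cutoff, include_query = TRUE,
                               query = query)
  records <- read_activity_records(bioactivity, targets = expansion)
  labeled <- label_compounds(records)
  held <- withhold_query_actives(labeled, query_uniprot)
  if (!held$evaluable) {
    return(list(results = NULL, evaluable = FALSE, labeled = labeled,
                expansion = expansion))
  }
  if (is.character(library)) library <- read_library(library)

  balanced <- undersample(held$training, seed = config$seed)
  train_fp <- compute_fingerprints(balanced, fp_spec)
  y <- as.integer(balanced$label[match(train_fp$keys, balanced$inchikey)] == "active")
  withheld_fp <- compute_fingerprints(held$withheld, fp_spec)
  lib_fp <- compute_fingerprints(library, fp_spec)

  models <- list(); scores <- list(); rows <- list()
  for (kind in config$models) {
    m <- train_model(train_fp, y, kind, config)
    sw <- score_library(m, withheld_fp)
    sl <- score_library(m, lib_fp)
    models[[kind]] <- m
    scores[[kind]] <- list(withheld = sw, library = sl)
    rows[[kind]] <- compare_scores(sw, sl, model = kind, test = test)
  }
  list(results = dplyr::bind_rows(rows), models = models, scores = scores,
       training = balanced, withheld = held$withheld, labeled = labeled,
       expansion = expansion, features = list(train = train_fp,
                                              withheld = withheld_fp,
                                              library = lib_fp),
       evaluable = TRUE)
}
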