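# End-to-end orchestration: three starting points, seven stages, per-stage
# output folders, and a machine-readable summary.

#' Assemble a pipeline run configuration
#'
#' Exactly one starting point must be supplied: a target accession
#' (`uniprot_id`; runs the full pipeline), a pre-selected target list
#' (`target_list`; skips expansion), or a pre-labeled compound list
#' (`compound_list`; skips expansion and retrieval).
#'
#' @param uniprot_id query target accession (starting point 1).
#' @param target_list tibble/CSV of targets with `uniprot_id`,
#'   `percent_identity` columns (starting point 2).
#' @param compound_list labeled compounds with `smiles` and `label` columns
#'   (starting point 3).
#' @param homology,bioactivity offline fixture tables (paths or data frames)
#'   backing the expansion and retrieval stages.
#' @param library screening library: an `lvs_library` or a path readable by
#'   [read_library()].
#' @param identity_cutoff homology identity cutoff (percent, default 40).
#' @param potency_cutoff_nm,inhibition_cutoff_pct labeling cutoffs.
#' @param value_type override for the majority-rule assay type.
#' @param conflict_policy cross-target labeling policy.
#' @param fp_spec a [fingerprint_spec()].
#' @param training a [training_config()].
#' @param top_fraction hit-list fraction (default 0.01).
#' @param n_clusters k for library clustering.
#' @param out_dir output directory.
#' @param seed run seed (propagated to every stochastic step).
#' @param make_plots write diagnostic plots (PDF) alongside the tables.
#' @export
run_config <- function(uniprot_id = NULL, target_list = NULL, compound_list = NULL,
                       homology = NULL, bioactivity = NULL, library = NULL,
                       identity_cutoff = 40, potency_cutoff_nm = 1000,
                       inhibition_cutoff_pct = 50, value_type = NULL,
                       conflict_policy = "pooled-median",
                       fp_spec = fingerprint_spec(),
                       training = training_config(seed = seed),
                       top_fraction = 0.01, n_clusters = 100,
                       out_dir = tempfile("lvs_run"), seed = 1,
                       make_plots = FALSE) {
  starts <- c(target_id = !is.null(uniprot_id),
              target_list = !is.null(target_list),
              compound_list = !is.null(compound_list))
  if (sum(starts) != 1) {
    stop("exactly one starting point must be given (uniprot_id, target_list, ",
         "or compound_list)", call. = FALSE)
  }
  structure(list(starting_point = names(starts)[starts],
                 uniprot_id = uniprot_id, target_list = target_list,
                 compound_list = compound_list, homology = homology,
                 bioactivity = bioactivity, library = library,
                 identity_cutoff = identity_cutoff,
                 potency_cutoff_nm = potency_cutoff_nm,
                 inhibition_cutoff_pct = inhibition_cutoff_pct,
                 value_type = value_type, conflict_policy = conflict_policy,
                 fp_spec = fp_spec, training = training,
                 top_fraction = top_fraction, n_clusters = n_clusters,
                 out_dir = out_dir, seed = as.integer(seed),
                 make_plots = make_plots),
            class = "lvs_run_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

#' Run the virtual-screening pipeline
#'
#' Executes target expansion, compound retrieval and labeling, vectorization,
#' model training, library screening, post-screening analysis, and report
#' generation, skipping the stages before the chosen starting point. Each
#' stage writes its tables to its own folder under `out_dir`; a summary JSON
#' (deterministic given config + seed; no timestamps) and the ranked hit list
#' are written at the end.
#'
#' @param config an [run_config()].
#' @return invisibly, a list with the per-stage objects and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lvs_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, starting_point = config$starting_point)

  expansion <- NULL; labeled <- NULL
  if (config$starting_point == "target_id") {
    query <- target_query(config$uniprot_id)
    backend <- homology_backend_fixture(config$homology)
    hits <- search_homologs(backend, query)
    expansion <- filter_homologs(hits, config$identity_cutoff,
                                 include_query = TRUE, query = query)
    write_table(expansion, file.path(stage_dir(config, "01_target_expansion"),
                                     "expanded_targets.csv"))
  } else if (config$starting_point == "target_list") {
    tl <- config$target_list
    if (is.character(tl)) tl <- readr::read_csv(tl, show_col_types = FALSE)
    expansion <- tibble::as_tibble(tl)
  }
  summary$n_targets <- if (is.null(expansion)) 0L else nrow(expansion)

  if (config$starting_point == "compound_list") {
    cl <- config$compound_list
    if (is.character(cl)) cl <- readr::read_csv(cl, show_col_types = FALSE)
    std <- standardize_molecules(cl$smiles)
    labeled <- tibble::tibble(inchikey = std$inchikey, smiles = std$smiles,
                              label = cl$label[as.integer(gsub("\\D", "", std$source_id))],
                              evidence_count = 1L)
    labeled <- labeled[!duplicated(labeled$inchikey), ]
    summary$value_type <- "user"
  } else {
    records <- read_activity_records(config$bioactivity, targets = expansion)
    vt <- select_primary_value_type(records)
    write_table(attr(vt, "counts"),
                file.path(stage_dir(config, "02_compound_retrieval"),
                          "value_type_distribution.csv"))
    labeled <- label_compounds(records,
                               value_type = config$value_type,
                               potency_cutoff_nm = config$potency_cutoff_nm,
                               inhibition_cutoff_pct = config$inhibition_cutoff_pct,
                               conflict_policy = config$conflict_policy)
    d2 <- stage_dir(config, "02_compound_retrieval")
    write_table(labeled[labeled$label == "active", ], file.path(d2, "actives.csv"))
    write_table(labeled[labeled$label == "inactive", ], file.path(d2, "inactives.csv"))
    summary$value_type <- attr(labeled, "value_type")
    summary$n_records <- nrow(records)
  }
  summary$n_active <- sum(labeled$label == "active")
  summary$n_inactive <- sum(labeled$label == "inactive")

  balanced <- undersample(labeled, seed = config$seed)
  train_fp <- compute_fingerprints(balanced, config$fp_spec)
  y <- as.integer(balanced$label[match(train_fp$keys, balanced$inchikey)] == "active")
  d3 <- stage_dir(config, "03_vectorization")
  write_fingerprints(train_fp, file.path(d3, "training_fingerprints.csv"))
  summary$n_training <- length(y)
  summary$fingerprint <- format(config$fp_spec)

  d4 <- stage_dir(config, "04_model_training")
  models <- list()
  for (kind in config$training$models) {
    m <- train_model(train_fp, y, kind, config$training)
    models[[kind]] <- m
    write_table(m$cv_metrics, file.path(d4, paste0(kind, "_cv_metrics.csv")))
    write_table(m$grid_search, file.path(d4, paste0(kind, "_grid_search.csv")))
    roc_df <- dplyr::bind_rows(lapply(seq_along(m$roc), function(i)
      dplyr::mutate(m$roc[[i]], fold = i)))
    write_table(roc_df, file.path(d4, paste0(kind, "_roc_points.csv")))
    if (config$make_plots) plot_roc(m, file.path(d4, paste0(kind, "_roc.pdf")))
    summary[[paste0(kind, "_cv_auc")]] <- m$cv_mean$auc
    summary[[paste0(kind, "_hyperparameters")]] <- lapply(
      m$chosen_hyperparameters, function(v) paste(v, collapse = "x"))
  }

  library <- config$library
  if (is.character(library)) library <- read_library(library)
  lib_fp <- compute_fingerprints(library, config$fp_spec)
  scores <- lapply(models, score_library, features = lib_fp)
  d5 <- stage_dir(config, "05_virtual_screening")
  for (kind in names(scores)) {
    write_table(tibble::tibble(inchikey = names(scores[[kind]]),
                               score = unname(scores[[kind]])),
                file.path(d5, paste0(kind, "_scores.csv")))
  }
  summary$n_library <- nrow(library)

  smi_map <- stats::setNames(library$smiles, library$inchikey)
  screen <- rank_and_merge(scores, top_fraction = config$top_fraction,
                           smiles = smi_map)
  top <- attr(screen, "top_hits")

  d6 <- stage_dir(config, "06_postvs_analysis")
  dist <- summarize_scores(screen)
  write_table(dist$histogram, file.path(d6, "score_histograms.csv"))
  write_table(dist$stats, file.path(d6, "score_stats.csv"))
  profiles <- profile_compounds(top)
  write_table(profiles, file.path(d6, "top_hit_properties.csv"))
  if (config$make_plots) {
    plot_score_distributions(screen, file.path(d6, "score_distributions.pdf"))
    plot_property_distributions(profiles, file.path(d6, "top_hit_properties.pdf"))
  }
  summary$mean_qed_top_hits <- mean(profiles$qed, na.rm = TRUE)

  d7 <- stage_dir(config, "07_data_processing")
  write_table(screen, file.path(d7, "full_compound_list.csv"))
  write_table(top, file.path(d7, "top_virtual_hits.csv"))
  summary$n_top_hits <- nrow(top)
  summary$top_k_per_list <- attr(screen, "top_k_per_list")
  summary$config_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, expansion = expansion, labeled = labeled,
                 models = models, screen = screen, top_hits = top,
                 profiles = profiles, library = library,
                 features = list(train = train_fp, library = lib_fp)))
}
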