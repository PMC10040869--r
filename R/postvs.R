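# Post-screening analysis: physicochemical profiling, score distributions,
# chemical-space clustering, and the Tanimoto-similarity baseline.

#' Physicochemical and drug-likeness profile
#'
#' Computes QED plus molecular weight, logP, hydrogen-bond acceptor and donor
#' counts, rotatable bonds, and topological polar surface area for every
#' compound. Descriptors are delegated to OpenBabel (acceptor/donor and logP
#' values follow its conventions); aromatic-ring perception uses ChemmineR;
#' QED is evaluated from the published desirability constants.
#'
#' @param x data frame with `smiles` and `inchikey` columns (library, labeled
#'   set, or screen report), or a character vector of SMILES.
#' @return tibble with one row per compound: `inchikey`, `smiles`, `qed`,
#'   `mw`, `logp`, `hba`, `hbd`, `rotatable_bonds`, `tpsa`, `aromatic_rings`,
#'   `alerts`. Rows whose descriptors fail are flagged via `profile_ok`.
#' @export
profile_compounds <- function(x) {
  if (is.character(x)) {
    x <- standardize_molecules(x)
  }
  stopifnot(is.data.frame(x), all(c("smiles", "inchikey") %in% names(x)), nrow(x) > 0)
  smiles <- x$smiles
  d <- ob_descriptors(smiles, c("MW", "logP", "TPSA", "HBA1", "HBD", "rotors"))
  num <- function(v) suppressWarnings(as.numeric(v))

  arom <- aromatic_ring_counts(smiles)
  alert_counts <- integer(length(smiles))
  for (pat in QED_ALERT_SMARTS) {
    hit <- ob_smarts_match(smiles, pat)
    idx <- match(hit, ob_titles(length(smiles)))
    idx <- idx[!is.na(idx)]
    alert_counts[idx] <- alert_counts[idx] + 1L
  }

  out <- tibble::tibble(
    inchikey = x$inchikey,
    smiles = smiles,
    mw = num(d$MW),
    logp = num(d$logP),
    tpsa = num(d$TPSA),
    hba = as.integer(num(d$HBA1)),
    hbd = as.integer(num(d$HBD)),
    rotatable_bonds = as.integer(num(d$rotors)),
    aromatic_rings = arom,
    alerts = alert_counts
  )
  out$profile_ok <- stats::complete.cases(out[, c("mw", "logp", "tpsa", "hba",
                                                  "hbd", "rotatable_bonds")])
  out$qed <- NA_real_
  ok <- out$profile_ok & !is.na(out$aromatic_rings)
  if (any(ok)) {
    out$qed[ok] <- qed_score(out$mw[ok], out$logp[ok], out$hba[ok], out$hbd[ok],
                             out$tpsa[ok], out$rotatable_bonds[ok],
                             out$aromatic_rings[ok], out$alerts[ok])
  }
  if (any(!out$profile_ok)) {
    warning(sum(!out$profile_ok), " compound(s) flagged: descriptor calculation failed",
            call. = FALSE)
  }
  dplyr::relocate(out, "qed", .after = "smiles")
}

#' @rdname profile_compounds
#' @param smiles a single SMILES string.
#' @export
profile_compound <- function(smiles) {
  profile_compounds(standardize_molecule(smiles))
}

aromatic_ring_counts <- function(smiles) {
  sdf <- quiet_smiles2sdf(smiles)
  valid <- attr(sdf, "valid")
  res <- rep(NA_integer_, length(smiles))
  if (any(valid)) {
    r <- suppressMessages(ChemmineR::rings(sdf$set, type = "count", arom = TRUE))
    if (is.null(dim(r))) r <- matrix(r, nrow = 1, dimnames = list(NULL, names(r)))
    res[valid] <- as.integer(r[, "AROMATIC"])
  }
  res
}

#' Score-distribution summaries
#'
#' Histogram tables on a fixed 50-bin grid over \[0, 1\] plus summary
#' statistics per model.
#'
#' @param report an `lvs_screen` report (or a data frame with `score_*`
#'   columns).
#' @return list with `histogram` (tibble: model, bin_low, bin_high, count) and
#'   `stats` (tibble: model, n, mean, sd, quantiles).
#' @export
summarize_scores <- function(report) {
  cols <- grep("^score_", names(report), value = TRUE)
  if (!length(cols)) stop("report has no score_* columns", call. = FALSE)
  breaks <- seq(0, 1, length.out = 51)
  hist_tbl <- dplyr::bind_rows(lapply(cols, function(cl) {
    s <- report[[cl]]
    cnt <- as.integer(table(cut(s, breaks, include.lowest = TRUE)))
    tibble::tibble(model = sub("^score_", "", cl),
                   bin_low = breaks[-51], bin_high = breaks[-1], count = cnt)
  }))
  stats_tbl <- dplyr::bind_rows(lapply(cols, function(cl) {
    s <- report[[cl]]
    q <- stats::quantile(s, c(0.25, 0.5, 0.75))
    tibble::tibble(model = sub("^score_", "", cl), n = length(s),
                   mean = mean(s), sd = stats::sd(s),
                   q25 = q[[1]], median = q[[2]], q75 = q[[3]])
  }))
  list(histogram = hist_tbl, stats = stats_tbl)
}

#' Cluster a screening library in fingerprint space
#'
#' k-means on the raw fingerprint bits with multiple seeded restarts (best
#' within-cluster sum of squares kept). Per-cluster score statistics identify
#' the top-scoring cluster.
#'
#' @param features an `lvs_fpmat`.
#' @param scores numeric score vector named by InChI key (typically the RF
#'   scores).
#' @param n_clusters number of clusters (default 100; must be between 2 and
#'   the number of compounds).
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 10).
#' @param iter_max k-means iteration cap per restart.
#' @return list with `assignments` (tibble inchikey, cluster, score),
#'   `summary` (per-cluster n, mean/median score), and `top_cluster` (id with
#'   the highest mean score).
#' @export
cluster_library <- function(features, scores, n_clusters = 100, seed = 1,
                            n_restarts = 10, iter_max = 30) {
  stopifnot(inherits(features, "lvs_fpmat"))
  n <- nrow(features$bits)
  if (n_clusters > n) stop("n_clusters exceeds the number of compounds", call. = FALSE)
  if (n_clusters < 2) stop("n_clusters must be at least 2", call. = FALSE)
  s <- scores[features$keys]
  if (n_clusters == n) {
    # degenerate k: every compound is its own cluster
    cluster <- seq_len(n)
  } else {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    km <- suppressWarnings(stats::kmeans(features$bits, centers = n_clusters,
                                         nstart = n_restarts, iter.max = iter_max))
    cluster <- as.integer(km$cluster)
  }
  assignments <- tibble::tibble(inchikey = features$keys,
                                cluster = cluster,
                                score = unname(s))
  summary <- assignments |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n = dplyr::n(), mean_score = mean(.data$score),
                     median_score = stats::median(.data$score),
                     q75 = stats::quantile(.data$score, 0.75), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_score))
  list(assignments = assignments, summary = summary,
       top_cluster = summary$cluster[1])
}

#' Two-dimensional stochastic-neighbour embedding of chemical space
#'
#' Exact t-SNE on the fingerprint bits (implemented in the package), with a
#' deterministic PCA initialization: a fixed seed gives an identical embedding,
#' and duplicate compounds land at coincident coordinates. Intended for
#' visualization only.
#'
#' @param features an `lvs_fpmat` (or numeric matrix).
#' @param groups optional group label per compound, carried into the output.
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (default 30; clamped for tiny inputs).
#' @param max_iter gradient iterations.
#' @return tibble with `inchikey` (when available), `dim1`, `dim2`, `group`.
#' @export
embed_2d <- function(features, groups = NULL, seed = 1, perplexity = 30,
                     max_iter = 300) {
  x <- if (inherits(features, "lvs_fpmat")) features$bits else as.matrix(features)
  keys <- if (inherits(features, "lvs_fpmat")) features$keys else rownames(x)
  y <- tsne_embed(x, perplexity = perplexity, max_iter = max_iter, seed = seed)
  out <- tibble::tibble(dim1 = y[, 1], dim2 = y[, 2])
  if (!is.null(keys)) out <- dplyr::bind_cols(tibble::tibble(inchikey = keys), out)
  out$group <- if (is.null(groups)) "all" else as.character(groups)
  out
}

#' Tanimoto similarity search against a library
#'
#' The classical ligand-based baseline: rank the library by Tanimoto
#' coefficient to a query compound under a fingerprint spec.
#'
#' @param query a SMILES string (standardized internally).
#' @param features an `lvs_fpmat` for the library.
#' @return tibble `inchikey`, `tc`, sorted by descending coefficient (ties by
#'   InChI key). An all-zero query fingerprint yields Tc 0 everywhere with a
#'   warning.
#' @export
tanimoto_search <- function(query, features) {
  stopifnot(inherits(features, "lvs_fpmat"))
  q <- standardize_molecule(query)
  qfp <- compute_fingerprints(q, features$spec)
  qv <- qfp$bits[1, ]
  if (sum(qv) == 0) {
    warning("query fingerprint has no bits set; all Tc are 0", call. = FALSE)
  }
  tc <- unname(tanimoto(qv, features$bits))
  out <- tibble::tibble(inchikey = features$keys, tc = tc)
  dplyr::arrange(out, dplyr::desc(.data$tc), .data$inchikey)
}
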