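#' Score a screening library with a trained model
#'
#' The library fingerprints must have been computed under the same
#' specification as the training fingerprints; a mismatch is a fatal
#' configuration error naming both specs.
#'
#' @param model an `lvs_classifier` from [train_model()].
#' @param features an `lvs_fpmat` for the library.
#' @return named numeric vector of probability-of-active scores in \[0, 1\]
#'   (names = InChI keys).
#' @export
score_library <- function(model, features) {
  stopifnot(inherits(model, "lvs_classifier"), inherits(features, "lvs_fpmat"))
  if (!is.null(model$fp_spec) && !identical(unclass(model$fp_spec),
                                            unclass(features$spec))) {
    stop(sprintf("fingerprint spec mismatch: model trained on %s, library is %s",
                 format(model$fp_spec), format(features$spec)), call. = FALSE)
  }
  sc <- predict_engine(model$model, features$bits)
  names(sc) <- features$keys
  sc
}

#' Rank per-model scores and merge the top hit lists
#'
#' Each model's compounds are ranked 1..N by descending score, ties broken by
#' InChI key so the ordering is strict and reproducible. The ensemble rank is
#' the arithmetic mean of the per-model ranks. The top-hit list is the union of
#' the top `ceil(top_fraction * N)` compounds from each model's ranking and
#' from the ensemble ranking, deduplicated by InChI key.
#'
#' @param scores_by_model named list of score vectors (names = InChI keys);
#'   all models must cover the identical compound set.
#' @param top_fraction fraction in (0, 1\] (default 0.01, the "top 1 percent").
#' @param smiles optional named character vector (by InChI key) carried into
#'   the report.
#' @return an `lvs_screen` report: tibble with per-model scores and ranks,
#'   `ensemble_rank`, and `top_hit`; rows sorted by ensemble rank. The top-hit
#'   subset is in attribute `"top_hits"`.
#' @export
rank_and_merge <- function(scores_by_model, top_fraction = 0.01, smiles = NULL) {
  stopifnot(is.list(scores_by_model), length(scores_by_model) >= 1,
            top_fraction > 0, top_fraction <= 1)
  if (is.null(names(scores_by_model)) || any(!nzchar(names(scores_by_model)))) {
    stop("scores_by_model must be a named list (model names)", call. = FALSE)
  }
  keysets <- lapply(scores_by_model, function(s) sort(names(s)))
  if (length(unique(keysets)) != 1) {
    stop("models scored different compound sets; cannot merge", call. = FALSE)
  }
  keys <- sort(names(scores_by_model[[1]]))
  n <- length(keys)
  k <- ceiling(top_fraction * n)

  out <- tibble::tibble(inchikey = keys)
  ranks <- matrix(NA_integer_, n, length(scores_by_model))
  for (j in seq_along(scores_by_model)) {
    s <- scores_by_model[[j]][keys]
    ord <- order(-s, keys)
    r <- integer(n); r[ord] <- seq_len(n)
    ranks[, j] <- r
    out[[paste0("score_", names(scores_by_model)[j])]] <- unname(s)
    out[[paste0("rank_", names(scores_by_model)[j])]] <- r
  }
  out$ensemble_rank <- rowMeans(ranks)
  ens_ord <- order(out$ensemble_rank, keys)
  top_keys <- unique(c(
    unlist(lapply(seq_along(scores_by_model), function(j) keys[ranks[, j] <= k])),
    keys[ens_ord[seq_len(k)]]
  ))
  out$top_hit <- out$inchikey %in% top_keys
  if (!is.null(smiles)) out$smiles <- unname(smiles[out$inchikey])
  out <- out[ens_ord, , drop = FALSE]
  structure(out, class = c("lvs_screen", class(out)),
            top_hits = out[out$top_hit, , drop = FALSE],
            top_k_per_list = k)
}
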