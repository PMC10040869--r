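#' Training configuration
#'
#' Defaults follow the platform's published hyperparameter grids: random
#' forest over `num_trees` in {50, 100, 200} and `max_depth` in
#' {4, 6, 10, 12}; MLP over hidden layer sizes {(50,50,50), (50,50), (50)},
#' activation {tanh, relu}, and L2 alpha {0.01, 0.0001}. Grid search is scored
#' by mean cross-validated AUC over `n_folds` stratified folds (default 10).
#'
#' @param models which model kinds to train (`"rf"`, `"mlp"`).
#' @param rf_grid named list of RF hyperparameter vectors.
#' @param mlp_grid named list of MLP hyperparameter vectors (`hidden` is a
#'   list of integer vectors).
#' @param n_folds folds for cross-validation (>= 2).
#' @param seed run seed; all derived randomness (undersampling, folds, model
#'   fits) is deterministic given it.
#' @export
training_config <- function(models = c("rf", "mlp"),
                            rf_grid = list(num_trees = c(50, 100, 200),
                                           max_depth = c(4, 6, 10, 12)),
                            mlp_grid = list(hidden = list(c(50, 50, 50), c(50, 50), 50),
                                            activation = c("tanh", "relu"),
                                            alpha = c(0.01, 0.0001)),
                            n_folds = 10, seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  stopifnot(n_folds >= 2, length(rf_grid) > 0, length(mlp_grid) > 0)
  structure(list(models = models, rf_grid = rf_grid, mlp_grid = mlp_grid,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "lvs_training_config")
}

#' Balance classes by random undersampling
#'
#' The majority class is randomly downsampled without replacement to the
#' minority class size; the minority class is untouched. Deterministic under
#' `seed`.
#'
#' @param labeled an `lvs_labeled` tibble (or any data frame with a `label`
#'   column of "active"/"inactive").
#' @param seed RNG seed.
#' @export
undersample <- function(labeled, seed = 1) {
  tab <- table(labeled$label)
  if (length(tab) < 2 || any(tab == 0)) {
    stop("undersampling needs both classes present; got ",
         paste(names(tab), tab, sep = "=", collapse = ", "), call. = FALSE)
  }
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  keep_maj <- sort(sample(which(labeled$label == majority), min(tab)))
  out <- labeled[sort(c(which(labeled$label == minority), keep_maj)), , drop = FALSE]
  out
}

#' Confusion-matrix performance metrics
#'
#' Computes precision, recall (sensitivity), specificity, F1, geometric mean
#' `sqrt(recall * specificity)`, and the index of balanced accuracy
#' `(1 + alpha * (recall - specificity)) * recall * specificity`. Ratios with
#' a zero denominator are reported as 0 and flagged.
#'
#' @param tp,fp,tn,fn confusion counts (non-negative; at least one positive).
#' @param iba_alpha IBA dominance weight (default 0.1).
#' @return one-row tibble of metrics plus a `degenerate` flag.
#' @export
compute_metrics <- function(tp, fp, tn, fn, iba_alpha = 0.1) {
  stopifnot(all(c(tp, fp, tn, fn) >= 0), tp + fp + tn + fn > 0)
  div <- function(num, den) if (den == 0) 0 else num / den
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  specificity <- div(tn, tn + fp)
  f1 <- div(2 * precision * recall, precision + recall)
  gm <- sqrt(recall * specificity)
  iba <- (1 + iba_alpha * (recall - specificity)) * (recall * specificity)
  degenerate <- (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0) ||
    (precision + recall == 0)
  tibble::tibble(precision = precision, recall = recall,
                 specificity = specificity, f1 = f1,
                 geometric_mean = gm, iba = iba, degenerate = degenerate)
}

# ROC/AUC via pROC (trapezoidal over the full curve); returns auc + the curve.
roc_auc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(fpr = rev(1 - r$specificities),
                          tpr = rev(r$sensitivities))
  list(auc = as.numeric(pROC::auc(r)), curve = curve)
}

# Stratified fold assignment; redraws with a shifted seed if any fold ends up
# single-class (possible only for tiny class sizes).
make_folds <- function(y, k, seed) {
  for (attempt in 0:10) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    set.seed(seed + attempt)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    ok <- all(vapply(seq_len(k), function(f) length(unique(y[fold == f])) == 2, TRUE))
    if (ok) {
      if (attempt > 0) warning("fold redraw needed (single-class fold)", call. = FALSE)
      return(fold)
    }
  }
  stop("could not build stratified folds with both classes in every fold", call. = FALSE)
}

ensure_colnames <- function(x) {
  if (is.null(colnames(x))) colnames(x) <- paste0("bit", seq_len(ncol(x)))
  x
}

fit_engine <- function(kind, params, x, y, seed) {
  x <- ensure_colnames(x)
  if (kind == "rf") {
    ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                   num.trees = params$num_trees, max.depth = params$max_depth,
                   probability = TRUE, seed = seed, num.threads = 1,
                   verbose = FALSE)
  } else {
    mlp_fit(x, y, hidden = params$hidden, activation = params$activation,
            alpha = params$alpha, seed = seed)
  }
}

predict_engine <- function(model, x) {
  x <- ensure_colnames(x)
  if (inherits(model, "ranger")) {
    as.vector(stats::predict(model, data = x, num.threads = 1,
                             verbose = FALSE)$predictions[, "1"])
  } else {
    predict(model, x)
  }
}

#' Cross-validate one hyperparameter setting
#'
#' Stratified `n_folds`-fold cross-validation with a fixed seed. Scores are
#' thresholded at 0.5 on the predicted-probability scale for the
#' confusion-based metrics; per-fold ROC curves and trapezoidal AUCs are
#' returned alongside.
#'
#' @param x feature matrix (rows align with `labels`).
#' @param labels binary vector (0/1).
#' @param kind `"rf"` or `"mlp"`.
#' @param params named list of hyperparameters for the engine.
#' @param n_folds number of folds.
#' @param seed RNG seed (fold split and per-fold fits derive from it).
#' @param iba_alpha IBA weight.
#' @return list with `metrics` (tibble, one row per fold, incl. `auc`) and
#'   `roc` (list of per-fold fpr/tpr tibbles).
#' @export
cross_validate <- function(x, labels, kind, params, n_folds = 10, seed = 1,
                           iba_alpha = 0.1) {
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  fold <- make_folds(y, n_folds, seed)
  res <- vector("list", n_folds)
  rocs <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    model <- fit_engine(kind, params, x[tr, , drop = FALSE], y[tr], seed = seed + f)
    sc <- predict_engine(model, x[!tr, , drop = FALSE])
    yt <- y[!tr]
    pred <- as.integer(sc >= 0.5)
    m <- compute_metrics(tp = sum(pred == 1 & yt == 1), fp = sum(pred == 1 & yt == 0),
                         tn = sum(pred == 0 & yt == 0), fn = sum(pred == 0 & yt == 1),
                         iba_alpha = iba_alpha)
    ra <- roc_auc(yt, sc)
    res[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f, auc = ra$auc), m,
                                 tibble::tibble(n_test = sum(!tr)))
    rocs[[f]] <- ra$curve
  }
  list(metrics = dplyr::bind_rows(res), roc = rocs)
}

expand_param_grid <- function(kind, grid) {
  if (kind == "rf") {
    g <- expand.grid(num_trees = grid$num_trees, max_depth = grid$max_depth,
                     KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
  } else {
    combos <- list()
    for (h in grid$hidden) for (a in grid$activation) for (al in grid$alpha) {
      combos[[length(combos) + 1]] <- list(hidden = h, activation = a, alpha = al)
    }
    combos
  }
}

#' Train a classifier with exhaustive grid search
#'
#' Every combination in the configured grid is scored by mean cross-validated
#' AUC; the best one (first in grid order on ties) is refit on all the data.
#'
#' @param features an `lvs_fpmat` (or plain matrix) of training fingerprints.
#' @param labels binary vector (1 = active), aligned with the feature rows.
#' @param kind `"rf"` or `"mlp"`.
#' @param config a [training_config()].
#' @return an `lvs_classifier`: the fitted model, its chosen hyperparameters,
#'   the per-fold CV metrics of the winning setting, per-fold ROC curves, the
#'   full grid-search table, and the fingerprint spec it was trained under.
#' @export
train_model <- function(features, labels, kind = c("rf", "mlp"),
                        config = training_config()) {
  kind <- match.arg(kind)
  x <- if (inherits(features, "lvs_fpmat")) features$bits else as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("bit", seq_len(ncol(x)))
  spec <- if (inherits(features, "lvs_fpmat")) features$spec else NULL
  y <- as.numeric(labels)
  if (nrow(unique(x)) == 1) {
    warning("degenerate features: all rows identical", call. = FALSE)
  }
  grid <- expand_param_grid(kind, if (kind == "rf") config$rf_grid else config$mlp_grid)
  cvs <- lapply(grid, function(p) {
    cross_validate(x, y, kind, p, n_folds = config$n_folds, seed = config$seed)
  })
  mean_auc <- vapply(cvs, function(cv) mean(cv$metrics$auc), 0)
  best <- which.max(mean_auc)
  search <- tibble::tibble(
    setting = vapply(grid, function(p) paste(names(p), vapply(p, function(v)
      paste(v, collapse = "x"), ""), sep = "=", collapse = ", "), ""),
    mean_cv_auc = mean_auc
  )
  model <- fit_engine(kind, grid[[best]], x, y, seed = config$seed)
  structure(list(kind = kind,
                 chosen_hyperparameters = grid[[best]],
                 cv_metrics = cvs[[best]]$metrics,
                 cv_mean = dplyr::summarise(cvs[[best]]$metrics, dplyr::across(
                   c("auc", "precision", "recall", "specificity", "f1",
                     "geometric_mean", "iba"), mean)),
                 roc = cvs[[best]]$roc,
                 grid_search = search,
                 model = model,
                 fp_spec = spec,
                 seed = config$seed),
            class = "lvs_classifier")
}

#' @export
print.lvs_classifier <- function(x, ...) {
  hp <- vapply(x$chosen_hyperparameters, function(v) paste(v, collapse = "x"), "")
  cat(sprintf("<%s classifier: %s; mean CV AUC %.3f>\n", x$kind,
              paste(names(hp), hp, sep = "=", collapse = ", "),
              x$cv_mean$auc))
}
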