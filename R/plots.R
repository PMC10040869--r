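# Diagnostic figures (PDF; headless-safe device).

#' Plot per-fold ROC curves for a trained classifier
#' @param model an `lvs_classifier`.
#' @param path output PDF path.
#' @export
plot_roc <- function(model, path) {
  df <- dplyr::bind_rows(lapply(seq_along(model$roc), function(i)
    dplyr::mutate(model$roc[[i]], fold = factor(i))))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$fold)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%s cross-validation ROC (mean AUC %.3f)",
                                  toupper(model$kind), model$cv_mean$auc)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 5, device = grDevices::pdf)
  invisible(path)
}

#' Plot screening score distributions per model
#' @param screen an `lvs_screen` report.
#' @param path output PDF path.
#' @export
plot_score_distributions <- function(screen, path) {
  cols <- grep("^score_", names(screen), value = TRUE)
  df <- tidyr::pivot_longer(screen[, cols], dplyr::all_of(cols),
                            names_to = "model", values_to = "score")
  df$model <- sub("^score_", "", df$model)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0, fill = "steelblue") +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(x = "Prediction score", y = "Compounds") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 7, height = 4, device = grDevices::pdf)
  invisible(path)
}

#' Plot property distributions for a profiled compound set
#' @param profiles output of [profile_compounds()].
#' @param path output PDF path.
#' @export
plot_property_distributions <- function(profiles, path) {
  keep <- c("qed", "mw", "logp", "tpsa", "hba", "hbd", "rotatable_bonds")
  df <- tidyr::pivot_longer(profiles[, keep], dplyr::all_of(keep),
                            names_to = "property", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "darkorange") +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = NULL, y = "Compounds") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 8, height = 6, device = grDevices::pdf)
  invisible(path)
}

#' Bar plot of retrospective validation results
#' @param results the `results` tibble from [run_retrospective()].
#' @param path output PDF path.
#' @export
plot_retro_results <- function(results, path) {
  df <- tidyr::pivot_longer(
    results[, c("model", "mean_score_actives", "mean_score_library",
                "sem_actives", "sem_library")],
    c("mean_score_actives", "mean_score_library"),
    names_to = "set", values_to = "mean")
  df$sem <- ifelse(df$set == "mean_score_actives", df$sem_actives, df$sem_library)
  df$set <- ifelse(df$set == "mean_score_actives", "withheld actives", "library")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$mean, fill = .data$set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::scale_fill_manual(values = c("grey20", "grey60")) +
    ggplot2::labs(x = NULL, y = "Mean prediction score", fill = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4, device = grDevices::pdf)
  invisible(path)
}
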