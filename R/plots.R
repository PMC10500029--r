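# ggplot2 views of the main result types.

#' Plot per-sample selected-cell frequencies by label class
#'
#' @param freqs A [frequency_per_sample()] result.
#' @return A ggplot: one box per label class with per-sample points.
#' @export
plot_frequencies <- function(freqs) {
  ggplot2::ggplot(freqs,
                  ggplot2::aes(x = .data$label, y = .data$frequency)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "selected-cell frequency per sample") +
    ggplot2::theme_minimal()
}

#' Bar plot of cohort enrichment scores with MAD error bars
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot faceted by condition; the dashed line marks ES = 1
#'   (no enrichment).
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- object[!is.na(object$median_es), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type,
                                   y = .data$median_es)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$cell_type),
                      show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median_es - .data$mad_es,
                   ymax = .data$median_es + .data$mad_es), width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "enrichment score (median, MAD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar plot of top marker shifts by KS statistic
#'
#' @param object A `marker_shift` tibble.
#' @param scope Which scope to show (default `"all"`).
#' @param top_n How many markers (default 10).
#' @param ... Unused.
#' @return A ggplot of the top markers ranked by KS.
#' @export
autoplot.marker_shift <- function(object, scope = "all", top_n = 10, ...) {
  df <- object[object$scope == scope & !is.na(object$ks), ]
  df <- df[order(df$rank), ][seq_len(min(top_n, nrow(df))), ]
  df$marker <- factor(df$marker, levels = rev(df$marker))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks, y = .data$marker,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "KS statistic", y = NULL,
                  fill = "selected subset",
                  title = paste0("marker shifts (scope: ", scope, ")")) +
    ggplot2::theme_minimal()
}

#' Validation scores of a hyperparameter search
#'
#' @param object A `niche_fit`.
#' @param ... Unused.
#' @return A ggplot of per-trial validation scores.
#' @export
autoplot.niche_fit <- function(object, ...) {
  df <- object$report
  df$best <- df$trial == object$best_trial
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$val_score)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_filters),
                                     shape = .data$best), size = 2) +
    ggplot2::labs(x = "trial", y = "validation score",
                  colour = "filters", shape = "selected") +
    ggplot2::theme_minimal()
}
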