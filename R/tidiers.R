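## broom-style tidy()/glance() methods and ggplot2 autoplot() methods for
## the package's fitted objects and result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a position weight matrix into long format
#'
#' @param x A `mono_pwm` or `di_pwm`.
#' @param ... Unused.
#' @return Tibble (`position`, `letter`, `weight`); positions are 1-based
#'   columns, letters are bases or adjacent dinucleotides.
#' @export
tidy.pwm_model <- function(x, ...) {
  letters_ <- if (x$type == "mono") .BASES else .DINUCS
  tibble::tibble(position = rep(seq_len(nrow(x$weights)),
                                each = length(letters_)),
                 letter = rep(letters_, nrow(x$weights)),
                 weight = as.vector(t(x$weights)))
}

#' @export
glance.pwm_model <- function(x, ...) {
  tibble::tibble(model_id = x$id, type = x$type, length = x$L,
                 s_min = x$s_min, s_max = x$s_max)
}

#' @export
tidy.sitega_model <- function(x, ...) {
  out <- x$features
  out$weight <- x$weights
  out
}

#' @export
glance.sitega_model <- function(x, ...) {
  tibble::tibble(model_id = x$id, width = x$width,
                 n_features = nrow(x$features), intercept = x$intercept,
                 loo_cc = x$fitness)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, auc = x$auc,
                 n_points = nrow(x$points))
}

#' @export
tidy.combination_summary <- function(x, ...) {
  tibble::tibble(category = names(x$counts),
                 count = unname(x$counts),
                 fraction = unname(x$fractions))
}

#' @export
glance.combination_summary <- function(x, ...) {
  tibble::tibble(n_peaks = sum(x$counts),
                 sites_model_1 = unname(x$total_sites["model_1"]),
                 sites_model_2 = unname(x$total_sites["model_2"]),
                 cluster_fraction = x$cluster_fraction)
}

#' @export
tidy.chance_overlap_test <- function(x, ...) {
  tibble::tibble(set = c("real", "shuffled"),
                 d = c(x$real_counts[["d"]], x$background_counts[["d"]]),
                 a = c(x$real_counts[["a"]], x$background_counts[["a"]]),
                 frac_nonoverlap = c(x$observed_frac, x$expected_frac))
}

#' @export
glance.chance_overlap_test <- function(x, ...) {
  tibble::tibble(observed_frac = x$observed_frac,
                 expected_frac = x$expected_frac,
                 chi2 = x$chi2, df = x$df, p = x$p, n_fold = x$n_fold)
}

#' @export
tidy.discovery_result <- function(x, ...) x$occurrences

#' @export
glance.discovery_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, length = x$L,
                 n_occurrences = nrow(x$occurrences),
                 objective = x$objective, consensus = x$consensus)
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot: peak-level TP rate against FP rate with the diagonal
#'   chance line.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Fraction of recognized shuffled peaks (FP rate)",
                  y = "Fraction of recognized peaks (TP rate)",
                  title = sprintf("%s (AUC %.3f)", object$model_id,
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' PWM weight heatmap
#'
#' @param object A `mono_pwm` or `di_pwm`.
#' @param ... Unused.
#' @return A ggplot tile map of log-odds weights by position and letter.
#' @export
autoplot.pwm_model <- function(object, ...) {
  df <- tidy.pwm_model(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$letter,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "Matrix column", y = NULL, fill = "log-odds",
                  title = object$id) +
    ggplot2::theme_minimal()
}

#' Combination category bar chart
#'
#' @param object A `combination_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of category fractions, mirroring the usual
#'   red/orange/green/blue colouring of pairwise model comparisons.
#' @export
autoplot.combination_summary <- function(object, ...) {
  df <- tidy.combination_summary(object)
  df$category <- factor(df$category, c("a", "d", "b", "c", "neither"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(a = "red", d = "orange",
                                          b = "forestgreen", c = "blue",
                                          neither = "grey70")) +
    ggplot2::labs(x = "Category", y = "Fraction of peaks") +
    ggplot2::theme_minimal()
}

#' EMSA competition curves
#'
#' @param object An `emsa_curves` tibble.
#' @param ... Unused.
#' @return A ggplot of band intensity against competitor concentration
#'   (log axis), one line per oligo.
#' @export
autoplot.emsa_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$conc_ng,
                                       y = .data$intensity,
                                       group = .data$oligo_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Competitor (ng, log scale)", y = "Band intensity") +
    ggplot2::theme_minimal()
}

#' Scatterplot of two models' per-peak best scores
#'
#' The pairwise model-agreement view: each point is one peak, placed by its
#' best rescaled score under each model, with the calibrated thresholds as
#' solid lines.
#'
#' @param peaks Peak tibble.
#' @param model_1,model_2 Fitted models.
#' @param thresholds Optional numeric vector of two calibrated thresholds.
#' @return A ggplot.
#' @export
plot_score_scatter <- function(peaks, model_1, model_2, thresholds = NULL) {
  df <- tibble::tibble(x = .best_scores(peaks, model_1),
                       y = .best_scores(peaks, model_2))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s score", model_id(model_1)),
                  y = sprintf("%s score", model_id(model_2))) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_vline(xintercept = thresholds[1]) +
      ggplot2::geom_hline(yintercept = thresholds[2])
  }
  p
}
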