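#' Plot a stretch of a recording with optional annotations
#'
#' @param recording A `ns_recording`.
#' @param annotations Optional `ns_annotations` shaded behind the traces.
#' @param from_s,to_s Window to draw (seconds from recording start).
#' @return A ggplot.
#' @export
plot_recording <- function(recording, annotations = NULL, from_s = 0,
                           to_s = NULL) {
  rate <- rec_rate(recording)
  t <- recording$time_s - recording$time_s[1]
  to_s <- to_s %||% max(t)
  keep <- t >= from_s & t <= to_s
  df <- tibble::tibble(t = t[keep],
                       ax = recording$ax[keep], ay = recording$ay[keep],
                       az = recording$az[keep]) |>
    tidyr::pivot_longer(-"t", names_to = "axis", values_to = "g")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$g, colour = .data$axis))
  if (!is.null(annotations)) {
    ann <- dplyr::filter(tibble::as_tibble(annotations),
                         .data$hand == rec_hand(recording),
                         .data$end_s > from_s, .data$start_s < to_s)
    if (nrow(ann) > 0L) {
      p <- p + ggplot2::geom_rect(
        data = ann, inherit.aes = FALSE, alpha = 0.15,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf, fill = .data$label))
    }
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time since start (s)", y = "acceleration (g)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of two paired per-night measures
#'
#' @param derived,reference Paired numeric vectors.
#' @return A ggplot with the mean-difference line and 95% limits of
#'   agreement.
#' @export
plot_bland_altman <- function(derived, reference) {
  ba <- bland_altman(derived, reference)
  df <- tibble::tibble(avg = (derived + reference) / 2,
                       diff = derived - reference)
  ggplot2::ggplot(df, ggplot2::aes(.data$avg, .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "mean of measures", y = "difference (derived - reference)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-fold metric spread of a LOSO evaluation
#'
#' @param object A `ns_loso`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ns_loso
#' @export
autoplot.ns_loso <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "held-out subject value") +
    ggplot2::theme_minimal()
}

#' Persistence diagram plot
#'
#' @param object A `ns_pd`.
#' @param ... Unused.
#' @return A ggplot (birth on x, death on y, diagonal reference).
#' @method autoplot ns_pd
#' @export
autoplot.ns_pd <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$birth, .data$death,
                                   shape = .data$essential)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "birth", y = "death") +
    ggplot2::theme_minimal()
}

#' RFE elbow curve of a trained model
#'
#' @param object A `ns_model`.
#' @param ... Unused.
#' @return A ggplot of validation AUC against feature-set size.
#' @method autoplot ns_model
#' @export
autoplot.ns_model <- function(object, ...) {
  ggplot2::ggplot(object$rfe_curve,
                  ggplot2::aes(.data$n_features, .data$auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "features kept", y = "validation AUC") +
    ggplot2::theme_minimal()
}
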