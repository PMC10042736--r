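#' Plot an ROC curve
#'
#' @param object An `expulsion_roc` from [build_roc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.expulsion_roc <- function(object, ...) {
  dat <- tidy(object) %>% arrange(.data$fpr, .data$tpr)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("Expulsion-score ROC (AUC = %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
  if (!is.na(object$chosen_threshold)) {
    fin <- is.finite(object$thresholds)
    i <- which.min(abs(object$thresholds[fin] - object$chosen_threshold))
    p <- p + ggplot2::annotate("point", x = object$fpr[fin][i],
                               y = object$tpr[fin][i], colour = "red")
  }
  p
}

#' Plot per-condition median chromatin expansion over time
#'
#' @param median_curves Tibble from [render_summary()]`$median_curves` or
#'   [median_expansion()] output with a `condition` column added.
#' @param frame_interval Minutes per frame, used to label the x axis.
#' @return A ggplot.
#' @export
plot_median_expansion <- function(median_curves, frame_interval = NULL) {
  stopifnot(all(c("frame", "median_e") %in% names(median_curves)))
  dat <- median_curves
  xlab <- "Frame"
  if (!is.null(frame_interval)) {
    dat <- mutate(dat, frame = .data$frame * frame_interval)
    xlab <- "Time (min)"
  }
  aes <- if ("condition" %in% names(dat))
    ggplot2::aes(x = .data$frame, y = .data$median_e,
                 colour = .data$condition)
  else ggplot2::aes(x = .data$frame, y = .data$median_e)
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "Median chromatin expansion (fold)") +
    ggplot2::theme_minimal()
}

#' Plot the histogram of per-cell maximum chromatin expansion
#'
#' @param histogram Tibble from [render_summary()]`$histogram`.
#' @return A ggplot.
#' @export
plot_expansion_histogram <- function(histogram) {
  stopifnot(all(c("bin_low", "n") %in% names(histogram)))
  dat <- filter(histogram, is.finite(.data$bin_high))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_low + 0.125, y = .data$n)) +
    ggplot2::geom_col(width = diff(dat$bin_low[1:2]) * 0.9) +
    (if ("condition" %in% names(dat))
      ggplot2::facet_wrap(~condition) else NULL) +
    ggplot2::labs(x = "Maximum chromatin expansion (fold)", y = "Cells") +
    ggplot2::theme_minimal()
}
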