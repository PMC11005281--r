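# ggplot2 graphics for the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_line
#'   labs theme_minimal annotate
#' @export
ggplot2::autoplot

#' Bland-Altman plot of an agreement report
#'
#' Pair means against differences, with the bias (dashed) and the 95%
#' limits of agreement (dotted).
#'
#' @param object An `agreement_report` from [agreement].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- tibble(mean = object$means, difference = object$differences)
  ggplot(df, aes(x = mean, y = .data$difference)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$bias, linetype = "dashed") +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dotted") +
    labs(x = "Mean of measurements (degrees)",
         y = "Difference, prediction - reference (degrees)",
         title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                         object$bias, object$loa_low, object$loa_high)) +
    theme_minimal()
}

#' Training curve of a detector fit
#'
#' @param object A trained `detector_model`.
#' @param ... Unused.
#' @return A ggplot of the loss (and validation MRE when recorded) per
#'   epoch.
#' @export
autoplot.detector_model <- function(object, ...) {
  r <- tidy(object)
  p <- ggplot(r, aes(x = .data$epoch, y = .data$train_loss)) +
    geom_line() +
    labs(x = "Epoch", y = "Training loss", title = "Detector training") +
    theme_minimal()
  p
}

#' Display a phantom (or any grayscale image) with optional landmarks
#'
#' @param image H x W intensity matrix in `[0, 1]`, or a `phantom_sample`.
#' @param landmarks Optional [limb_landmarks] or data frame with `x`, `y`
#'   to overlay.
#' @param main Plot title.
#' @return Invisibly, `NULL`. Draws on the active base-graphics device
#'   (raster display; base graphics are the natural device for image
#'   matrices).
#' @export
plot_radiograph <- function(image, landmarks = NULL, main = "") {
  if (inherits(image, "phantom_sample")) {
    landmarks <- landmarks %||% image$landmarks
    image <- image$image
  }
  H <- nrow(image); W <- ncol(image)
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 asp = 1, xlab = "x", ylab = "y", main = main)
  graphics::rasterImage(image, 0.5, H + 0.5, W + 0.5, 0.5)
  if (!is.null(landmarks)) {
    xy <- if (inherits(landmarks, "limb_landmarks")) landmarks$xy else
      as.matrix(landmarks[, c("x", "y")])
    graphics::points(xy[, 1], xy[, 2], col = "red", pch = 3)
    if (!is.null(rownames(xy)))
      graphics::text(xy[, 1] + 4, xy[, 2], rownames(xy), col = "red",
                     cex = 0.6, adj = 0)
  }
  invisible(NULL)
}
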