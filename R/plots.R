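#' Plot a CT image
#'
#' Raster plot in a display window with a grayscale CT look.
#'
#' @param object a [ct_image()].
#' @param window HU display window.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.ct_image <- function(object, window = c(-1000, 2000), ...) {
  m <- hu_matrix(object)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$hu <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window, oob = scales_squish) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "HU", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

# minimal squish so we do not depend on scales directly
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot per-method metric averages of a report
#'
#' @param object a `redct_report` from [aggregate_metrics()].
#' @param metric `"psnr"` or `"ssim"`.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.redct_report <- function(object, metric = c("psnr", "ssim"), ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "psnr") "psnr_db" else "ssim"
  rows <- object$rows
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$method, y = .data[[ycol]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (metric == "psnr") "PSNR (dB)" else "SSIM") +
    ggplot2::theme_minimal()
}

#' Plot a training loss curve
#'
#' @param object a `train_result` from [train_model()].
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.train_result <- function(object, ...) {
  log <- object$log
  df <- tibble::tibble(
    iteration = rep(log$iteration, 3),
    term = rep(c("joint", "mse", "perceptual"), each = nrow(log)),
    loss = c(log$joint, log$mse, log$perceptual))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                   color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
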