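#' Tidy a metrics report
#'
#' @param x a `redct_report` from [aggregate_metrics()].
#' @param ... ignored.
#' @return the per-image records as a tibble (one row per image-method).
#' @export
tidy.redct_report <- function(x, ...) x$rows

#' @rdname tidy.redct_report
#' @return `glance()` returns one row per method with mean PSNR/SSIM and
#'   their display-rounded values.
#' @export
glance.redct_report <- function(x, ...) x$averages

#' Tidy a recursive encoder-decoder model
#'
#' @param x a `red_model`.
#' @param ... ignored.
#' @return one row per layer: type, weight/bias counts and shapes.
#' @export
tidy.red_model <- function(x, ...) {
  tibble::tibble(
    layer = seq_along(x$layers),
    type = vapply(x$layers, `[[`, character(1), "type"),
    n_weights = vapply(x$layers, function(l) length(l$W), numeric(1)),
    n_bias = vapply(x$layers, function(l) length(l$b), numeric(1)),
    weight_sd = vapply(x$layers, function(l) sd(as.vector(l$W)), numeric(1))
  )
}

#' @rdname tidy.red_model
#' @return `glance()` returns a one-row model summary with layer counts,
#'   recursion count, parameter total and the multiply-count complexity.
#' @export
glance.red_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    kernels_per_hidden_layer = x$config$kernels_per_hidden_layer,
    kernel_size = x$config$kernel_size,
    S = x$S,
    n_parameters = n_parameters(x),
    complexity = model_complexity(x$config, x$S),
    iteration = x$iteration
  )
}

#' Tidy a training run
#'
#' @param x a `train_result` from [train_model()].
#' @param ... ignored.
#' @return the per-iteration loss log as a tibble.
#' @export
tidy.train_result <- function(x, ...) x$log

#' @rdname tidy.train_result
#' @export
glance.train_result <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$log),
    final_joint = x$log$joint[nrow(x$log)],
    final_mse = x$log$mse[nrow(x$log)],
    final_perceptual = x$log$perceptual[nrow(x$log)],
    n_checkpoints = sum(!is.na(x$log$checkpoint))
  )
}
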