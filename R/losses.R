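#' Pixel-wise mean squared error loss
#'
#' `(1 / (W * H)) * sum((prediction - target)^2)` over a pair of equally
#' sized images; symmetric in its arguments. This is the pixel-comparison
#' half of the joint objective.
#'
#' @param prediction,target numeric matrices of identical shape.
#' @return non-negative scalar.
#' @examples
#' mse_loss(matrix(1, 4, 4), matrix(0, 4, 4))
#' @export
mse_loss <- function(prediction, target) {
  prediction <- as.matrix(prediction); target <- as.matrix(target)
  if (!all(dim(prediction) == dim(target))) stop("shape mismatch")
  mean((prediction - target)^2)
}

# gradient of mse_loss w.r.t. prediction
mse_loss_grad <- function(prediction, target) {
  2 * (prediction - target) / length(prediction)
}

#' Perceptual (feature-space) loss
#'
#' Runs both images through a frozen [feature_extractor()], takes the tapped
#' feature maps, and returns the squared distance normalized by the feature
#' map's spatial size only (channels are summed, not averaged):
#' `(1 / (W_i * H_i)) * sum((phi(prediction) - phi(target))^2)`.
#' Gradients flow to `prediction` only; the extractor stays frozen.
#'
#' @param prediction,target numeric matrices of identical shape.
#' @param extractor a [feature_extractor()].
#' @return non-negative scalar.
#' @export
perceptual_loss <- function(prediction, target, extractor) {
  perceptual_loss_impl(prediction, target, extractor, grad = FALSE)$value
}

perceptual_loss_impl <- function(prediction, target, extractor, grad = FALSE) {
  stopifnot(inherits(extractor, "feature_extractor"))
  prediction <- as.matrix(prediction); target <- as.matrix(target)
  if (!all(dim(prediction) == dim(target))) stop("shape mismatch")
  fp <- extractor_forward(extractor, prediction, keep = grad)
  ft <- extractor_forward(extractor, target, keep = FALSE)
  d <- fp$phi - ft$phi
  wh <- dim(d)[1] * dim(d)[2]
  value <- sum(d^2) / wh
  if (!grad) return(list(value = value))
  dpred <- extractor_backward(extractor, fp$cache, 2 * d / wh)
  list(value = value, grad = dpred)
}

#' Joint pixel + perceptual training loss
#'
#' The training objective: the pixel-wise MSE term plus the perceptual term,
#' `joint = mse + perceptual_weight * perceptual`. The default weight of 1
#' is the plain unweighted sum; the weight exists because the scale of the
#' perceptual term depends on the extractor.
#'
#' @inheritParams perceptual_loss
#' @param perceptual_weight non-negative scalar (default 1).
#' @return a `loss_report`: list with `mse_term`, `perceptual_term`, `joint`,
#'   `perceptual_weight`, and the extractor `provenance`.
#' @examples
#' fx <- feature_extractor(seed = 1)
#' a <- matrix(rnorm(144), 12, 12)
#' joint_loss(a, a, fx)$joint
#' @export
joint_loss <- function(prediction, target, extractor, perceptual_weight = 1) {
  if (perceptual_weight < 0) stop("perceptual_weight must be non-negative")
  mse <- mse_loss(prediction, target)
  per <- perceptual_loss(prediction, target, extractor)
  structure(list(mse_term = mse, perceptual_term = per,
                 joint = mse + perceptual_weight * per,
                 perceptual_weight = perceptual_weight,
                 provenance = extractor$provenance),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss_report> joint %.6g = mse %.6g + %.3g * perceptual %.6g\n",
              x$joint, x$mse_term, x$perceptual_weight, x$perceptual_term))
  invisible(x)
}

# joint loss with gradient w.r.t. prediction, used by training
joint_loss_grad <- function(prediction, target, extractor,
                            perceptual_weight = 1) {
  mse <- mse_loss(prediction, target)
  g <- mse_loss_grad(prediction, target)
  per <- 0
  if (perceptual_weight > 0 && !is.null(extractor)) {
    pl <- perceptual_loss_impl(prediction, target, extractor, grad = TRUE)
    per <- pl$value
    g <- g + perceptual_weight * pl$grad
  }
  list(report = list(mse_term = mse, perceptual_term = per,
                     joint = mse + perceptual_weight * per),
       grad = g)
}
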