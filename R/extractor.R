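#' Frozen convolutional feature extractor for the perceptual loss
#'
#' A compact stack of valid 3x3 convolutions with ReLU activations whose
#' weights are drawn once from a seeded Gaussian and then frozen; the
#' perceptual loss compares feature maps tapped from one of its layers.
#' Random frozen convolutional features are an established surrogate for
#' pretrained perceptual encoders; a loader hook ([load_extractor_weights()])
#' accepts externally supplied weights so a pretrained encoder can be
#' plugged in unchanged.
#'
#' Weights use a fan-in scaled Gaussian (He scaling) so feature magnitudes
#' stay comparable across layers.
#'
#' @param n_layers number of convolutional layers (default 4).
#' @param channels feature maps per layer (default 8).
#' @param kernel_size odd kernel side (default 3).
#' @param tap_index layer whose post-ReLU feature map is compared; defaults
#'   to the next-to-last layer.
#' @param seed integer seed for the frozen weights.
#' @return a `feature_extractor` object with `provenance = "seeded-random"`.
#' @examples
#' fx <- feature_extractor(seed = 1)
#' phi <- extract_features(fx, matrix(rnorm(64), 8, 8))
#' dim(phi)
#' @export
feature_extractor <- function(n_layers = 4, channels = 8, kernel_size = 3,
                              tap_index = n_layers - 1, seed = 1L) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  if (tap_index < 1 || tap_index > n_layers) {
    stop("tap_index out of range (1..", n_layers, ")")
  }
  k2 <- kernel_size^2
  layers <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_layers), function(l) {
      cin <- if (l == 1) 1L else channels
      sd <- sqrt(2 / (k2 * cin))
      list(type = "conv",
           W = matrix(rnorm(k2 * cin * channels, 0, sd), k2 * cin, channels),
           b = numeric(channels))
    })
  })
  structure(list(layers = layers, n_layers = as.integer(n_layers),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 tap_index = as.integer(tap_index), seed = as.integer(seed),
                 provenance = "seeded-random"),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf(
    "<feature_extractor> %d conv layers x %d channels, tap %d, %s weights\n",
    x$n_layers, x$channels, x$tap_index, x$provenance))
  invisible(x)
}

#' @rdname feature_extractor
#' @param extractor a `feature_extractor`.
#' @param weights list of `list(W, b)` per layer, shaped like the seeded
#'   defaults (conv weight matrices of k^2 * Cin rows).
#' @export
load_extractor_weights <- function(extractor, weights) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (length(weights) != extractor$n_layers) {
    stop("expected ", extractor$n_layers, " layers of weights")
  }
  for (l in seq_along(weights)) {
    if (!identical(dim(weights[[l]]$W), dim(extractor$layers[[l]]$W))) {
      stop("layer ", l, " weight shape mismatch")
    }
    extractor$layers[[l]]$W <- weights[[l]]$W
    extractor$layers[[l]]$b <- weights[[l]]$b %||% extractor$layers[[l]]$b
  }
  extractor$provenance <- "loaded-weights"
  extractor
}

# forward to the tap layer; optionally keep activations for backprop
extractor_forward <- function(extractor, x, keep = FALSE) {
  a <- array(x, dim = c(dim(x), 1L))
  need <- min_extractor_size(extractor)
  if (dim(a)[1] < need || dim(a)[2] < need) {
    stop("input too small for the extractor's tap depth (need >= ",
         need, " px)")
  }
  pre <- if (keep) vector("list", extractor$tap_index) else NULL
  act <- if (keep) vector("list", extractor$tap_index + 1L) else NULL
  if (keep) act[[1]] <- a
  for (l in seq_len(extractor$tap_index)) {
    z <- cpp_conv_fwd(a, extractor$layers[[l]]$W, extractor$layers[[l]]$b)
    a <- relu(z)
    if (keep) { pre[[l]] <- z; act[[l + 1L]] <- a }
  }
  list(phi = a, cache = if (keep) list(pre = pre, act = act) else NULL)
}

min_extractor_size <- function(extractor) {
  extractor$tap_index * (extractor$kernel_size - 1L) + 1L
}

# backpropagate a gradient on the tapped features to the input image
extractor_backward <- function(extractor, cache, dphi) {
  da <- dphi
  for (l in rev(seq_len(extractor$tap_index))) {
    dz <- da * (cache$pre[[l]] > 0)
    bw <- cpp_conv_bwd(cache$act[[l]], extractor$layers[[l]]$W, dz)
    da <- bw$dx
  }
  da[, , 1]
}

#' @rdname feature_extractor
#' @param x numeric matrix (single-channel image).
#' @return `extract_features()` returns the tapped feature map as an
#'   (H_i, W_i, channels) array.
#' @export
extract_features <- function(extractor, x) {
  stopifnot(inherits(extractor, "feature_extractor"))
  extractor_forward(extractor, as.matrix(x))$phi
}
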