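#' Configuration of the shallow residual encoder-decoder network
#'
#' The shallow network has `n_layers` layers: the first half are valid
#' (unpadded, stride-1) convolutions, the second half mirrored transposed
#' convolutions, so every spatial dimension shrinks by `kernel_size - 1` per
#' encoder layer and is exactly restored by the decoder. All hidden layers
#' carry `kernels_per_hidden_layer` feature maps; the last layer emits a
#' single detail map. Weights are initialized from a Gaussian with mean
#' `init_mean` and standard deviation `init_std`.
#'
#' `input_channels` defaults to 2 because each recursion stage receives the
#' previous stage's output stacked with the original noisy image (the first
#' stage receives the noisy image duplicated), and weight sharing requires a
#' fixed first-layer channel count.
#'
#' @param n_layers even layer count >= 4 (default 8).
#' @param kernels_per_hidden_layer feature maps per hidden layer (default 64).
#' @param kernels_last_layer feature maps of the final layer (default 1).
#' @param kernel_size odd kernel side (default 3).
#' @param input_channels channels of the stage input (default 2).
#' @param init_mean,init_std Gaussian weight initialization (0, 0.01).
#' @param residual keep the symmetric encoder-decoder skip additions and the
#'   global input-minus-detail residual (default `TRUE`); `FALSE` gives the
#'   plain non-residual variant for convergence comparisons.
#' @return a `red_config` object.
#' @export
red_config <- function(n_layers = 8, kernels_per_hidden_layer = 64,
                       kernels_last_layer = 1, kernel_size = 3,
                       input_channels = 2, init_mean = 0, init_std = 0.01,
                       residual = TRUE) {
  if (n_layers %% 2 != 0 || n_layers < 4) stop("n_layers must be even and >= 4")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  structure(list(n_layers = as.integer(n_layers),
                 kernels_per_hidden_layer = as.integer(kernels_per_hidden_layer),
                 kernels_last_layer = as.integer(kernels_last_layer),
                 kernel_size = as.integer(kernel_size),
                 input_channels = as.integer(input_channels),
                 init_mean = init_mean, init_std = init_std,
                 residual = isTRUE(residual)),
            class = "red_config")
}

# per-layer (type, in-channels, out-channels) plan for a config
layer_plan <- function(config) {
  m <- config$n_layers %/% 2
  K <- config$kernels_per_hidden_layer
  plan <- list()
  for (l in seq_len(m)) {
    plan[[l]] <- list(type = "conv",
                      cin = if (l == 1) config$input_channels else K,
                      cout = K)
  }
  for (j in seq_len(m)) {
    plan[[m + j]] <- list(type = "tconv", cin = K,
                          cout = if (j < m) K else config$kernels_last_layer)
  }
  plan
}

#' Build a weight-shared recursive residual encoder-decoder model
#'
#' One parameter set is created for the shallow network and reused at every
#' recursion stage, so the parameter count is independent of `S`.
#'
#' @param config a [red_config()].
#' @param seed integer seed for the Gaussian initialization.
#' @param S recursion count (default 5).
#' @return a `red_model` object.
#' @examples
#' model <- build_model(red_config(), seed = 1)
#' n_parameters(model)
#' @export
build_model <- function(config = red_config(), seed = 1L, S = 5L) {
  stopifnot(inherits(config, "red_config"))
  if (S < 1) stop("S must be >= 1")
  k2 <- config$kernel_size^2
  layers <- withr::with_seed(as.integer(seed), {
    lapply(layer_plan(config), function(pl) {
      dims <- if (pl$type == "conv") c(k2 * pl$cin, pl$cout) else
        c(pl$cin, k2 * pl$cout)
      list(type = pl$type,
           W = matrix(rnorm(prod(dims), config$init_mean, config$init_std),
                      dims[1], dims[2]),
           b = numeric(pl$cout))
    })
  })
  structure(list(config = config, S = as.integer(S), seed = as.integer(seed),
                 iteration = 0L, layers = layers),
            class = "red_model")
}

#' @rdname build_model
#' @param model a `red_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' @export
print.red_model <- function(x, ...) {
  cat(sprintf(
    "<red_model> %d layers (%d conv + %d deconv), %d kernels/hidden layer,\n",
    x$config$n_layers, x$config$n_layers %/% 2, x$config$n_layers %/% 2,
    x$config$kernels_per_hidden_layer))
  cat(sprintf("  S = %d recursions (weight-shared), %d parameters, iteration %d\n",
              x$S, n_parameters(x), x$iteration))
  invisible(x)
}

min_input_size <- function(config) {
  (config$n_layers %/% 2) * (config$kernel_size - 1) + 1
}

relu <- function(x) { x[x < 0] <- 0; x }

# forward pass of the shallow network on one stage input (H, W, C cube).
# Returns O (matrix), the detail map F, and (if keep) the cache needed for
# backpropagation.
shallow_forward <- function(layers, config, input, keep = FALSE) {
  m <- config$n_layers %/% 2
  if (dim(input)[1] < min_input_size(config) ||
      dim(input)[2] < min_input_size(config)) {
    stop("input too small for the valid-convolution chain (need >= ",
         min_input_size(config), " px)")
  }
  a <- input
  enc <- vector("list", m)    # post-ReLU encoder outputs
  pre <- vector("list", config$n_layers)
  act <- if (keep) vector("list", config$n_layers + 1L) else NULL
  if (keep) act[[1]] <- a
  for (l in seq_len(m)) {
    z <- cpp_conv_fwd(a, layers[[l]]$W, layers[[l]]$b)
    a <- relu(z)
    enc[[l]] <- a
    if (keep) { pre[[l]] <- z; act[[l + 1L]] <- a }
  }
  for (j in seq_len(m)) {
    l <- m + j
    z <- cpp_tconv_fwd(a, layers[[l]]$W, layers[[l]]$b)
    if (config$residual && j < m) z <- z + enc[[m - j]]
    a <- if (j < m) relu(z) else z
    if (keep) { pre[[l]] <- z; act[[l + 1L]] <- a }
  }
  detail <- a[, , 1]
  O <- if (config$residual) input[, , 1] - detail else detail
  list(O = O, detail = detail,
       cache = if (keep) list(input = input, pre = pre, act = act) else NULL)
}

# backpropagate dO through one shallow stage; returns gradient w.r.t. the
# stage input cube and per-layer weight gradients
shallow_backward <- function(layers, config, cache, dO) {
  m <- config$n_layers %/% 2
  n_l <- config$n_layers
  dF <- if (config$residual) -dO else dO
  da <- array(dF, dim = c(dim(dF), 1L))
  grads <- vector("list", n_l)
  denc <- vector("list", m)   # gradient accumulators for encoder outputs
  for (j in rev(seq_len(m))) {
    l <- m + j
    dz <- if (j < m) da * (cache$pre[[l]] > 0) else da
    if (config$residual && j < m) {
      denc[[m - j]] <- dz
    }
    bw <- cpp_tconv_bwd(cache$act[[l]], layers[[l]]$W, dz)
    grads[[l]] <- list(dw = bw$dw, db = as.vector(bw$db))
    da <- bw$dx
  }
  for (l in rev(seq_len(m))) {
    if (!is.null(denc[[l]])) da <- da + denc[[l]]
    dz <- da * (cache$pre[[l]] > 0)
    bw <- cpp_conv_bwd(cache$act[[l]], layers[[l]]$W, dz)
    grads[[l]] <- list(dw = bw$dw, db = as.vector(bw$db))
    da <- bw$dx
  }
  dI <- da
  if (config$residual) dI[, , 1] <- dI[, , 1] + dO
  list(dI = dI, grads = grads)
}

#' Apply the shallow network once
#'
#' Runs a single pass of the shallow residual encoder-decoder on a stage
#' input of `input_channels` channels: valid convolutions down, mirrored
#' transposed convolutions up, symmetric encoder-to-decoder skip additions,
#' ReLU after every layer except the last, and (in residual mode) a global
#' residual that subtracts the predicted detail map from the first input
#' channel.
#'
#' @param model a `red_model`.
#' @param input numeric array (H, W, C) with C = `input_channels`, or a
#'   matrix which is duplicated across channels.
#' @return single-channel numeric matrix of the input's spatial shape.
#' @export
forward_shallow <- function(model, input) {
  stopifnot(inherits(model, "red_model"))
  if (is.matrix(input)) {
    input <- array(rep(input, model$config$input_channels),
                   dim = c(dim(input), model$config$input_channels))
  }
  if (dim(input)[3] != model$config$input_channels) {
    stop("input must have ", model$config$input_channels, " channels")
  }
  shallow_forward(model$layers, model$config, input)$O
}

#' Run the full weight-shared recursion
#'
#' Stage inputs follow the cascade rule: the first stage receives the noisy
#' image duplicated across both channels, and every later stage receives the
#' previous stage's output stacked with the original noisy image. The same
#' parameter set is applied at every stage.
#'
#' @param model a `red_model`.
#' @param X numeric matrix, the normalized noisy image.
#' @param S optional stage-count override (defaults to `model$S`).
#' @return list with `output` (the final stage's image) and `trace`, a list
#'   with per-stage `inputs` (H x W x 2 arrays) and `outputs` (matrices).
#' @export
forward_recursive <- function(model, X, S = model$S) {
  stopifnot(inherits(model, "red_model"))
  if (S < 1) stop("S must be >= 1")
  X <- as.matrix(X)
  inputs <- vector("list", S)
  outputs <- vector("list", S)
  I <- array(c(X, X), dim = c(dim(X), 2L))
  for (s in seq_len(S)) {
    inputs[[s]] <- I
    O <- shallow_forward(model$layers, model$config, I)$O
    outputs[[s]] <- O
    if (s < S) I <- array(c(O, X), dim = c(dim(X), 2L))
  }
  list(output = outputs[[S]],
       trace = list(inputs = inputs, outputs = outputs))
}

# forward with caches kept, then backprop dO_S through all stages with
# weight-gradient accumulation (shared parameters). Returns output and grads.
recursive_forward_backward <- function(model, X, dO_fn) {
  S <- model$S
  config <- model$config
  layers <- model$layers
  caches <- vector("list", S)
  outputs <- vector("list", S)
  I <- array(c(X, X), dim = c(dim(X), 2L))
  for (s in seq_len(S)) {
    fw <- shallow_forward(layers, config, I, keep = TRUE)
    caches[[s]] <- fw$cache
    outputs[[s]] <- fw$O
    if (s < S) I <- array(c(fw$O, X), dim = c(dim(X), 2L))
  }
  loss <- dO_fn(outputs[[S]])
  dO <- loss$grad
  total <- NULL
  for (s in rev(seq_len(S))) {
    bw <- shallow_backward(layers, config, caches[[s]], dO)
    total <- if (is.null(total)) bw$grads else
      mapply(function(a, b) list(dw = a$dw + b$dw, db = a$db + b$db),
             total, bw$grads, SIMPLIFY = FALSE)
    if (s > 1) dO <- bw$dI[, , 1]
  }
  list(output = outputs[[S]], grads = total, loss = loss$report)
}

#' Denoise a CT image with a trained model
#'
#' Normalizes HU into the network domain, runs the weight-shared recursion,
#' and maps the final stage's output back to HU.
#'
#' @param model a `red_model`.
#' @param image a [ct_image()].
#' @param window HU normalization window (default `c(-1000, 2000)`).
#' @param S optional recursion-count override.
#' @return a denoised [ct_image()] of the same size.
#' @export
denoise_image <- function(model, image, window = c(-1000, 2000), S = model$S) {
  image <- as_ct_image(image)
  X <- normalize_hu(image, window)
  out <- forward_recursive(model, X, S = S)
  ct_image(denormalize_hu(out$output, window),
           pixel_spacing = pixel_spacing(image))
}

#' Multiply-count complexity of the recursive network
#'
#' Sums `n_(l-1) * f_l^2 * n_l` over the shallow network's layers (with
#' `n_0` the stage input channels) and multiplies by the recursion count,
#' since every stage re-executes the shared network.
#'
#' @param config a [red_config()].
#' @param S recursion count.
#' @return integer-valued complexity count.
#' @examples
#' model_complexity(red_config(), S = 1)
#' @export
model_complexity <- function(config = red_config(), S = 1L) {
  stopifnot(inherits(config, "red_config"))
  plan <- layer_plan(config)
  f2 <- config$kernel_size^2
  per_pass <- sum(vapply(plan, function(pl) pl$cin * f2 * pl$cout, numeric(1)))
  per_pass * S
}
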