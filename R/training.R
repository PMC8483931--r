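#' Training configuration
#'
#' Defaults follow the reference training protocol: learning rate 1e-5,
#' checkpoint every 1,000 iterations, stop at 50,000, 48 px patches. For
#' desk-scale experiments shrink `max_iterations`, `batch_size` and
#' `patch_size` (see the methods vignette for the toy profile used in the
#' test suite).
#'
#' @param learning_rate positive step size (default 1e-5).
#' @param max_iterations total iterations to run (default 50000).
#' @param checkpoint_every checkpoint cadence in iterations (default 1000);
#'   must not exceed `max_iterations`.
#' @param batch_size patches per stochastic gradient step (default 32).
#' @param patch_size square patch side the patch set must match (default 48).
#' @param seed integer seed driving batch sampling (and the default
#'   extractor).
#' @param perceptual_weight weight of the perceptual term (default 1).
#' @param optimizer `"adam"` (default; adaptive moments, beta 0.9/0.999) or
#'   `"sgd"`.
#' @param checkpoint_dir directory for checkpoints, or `NULL` to disable
#'   checkpoint writing.
#' @param window HU normalization window for the network domain.
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-5, max_iterations = 50000,
                         checkpoint_every = 1000, batch_size = 32,
                         patch_size = 48, seed = 1L, perceptual_weight = 1,
                         optimizer = c("adam", "sgd"), checkpoint_dir = NULL,
                         window = c(-1000, 2000)) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (checkpoint_every > max_iterations) {
    stop("checkpoint_every must not exceed max_iterations")
  }
  optimizer <- match.arg(optimizer)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 checkpoint_every = as.integer(checkpoint_every),
                 batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size), seed = as.integer(seed),
                 perceptual_weight = perceptual_weight, optimizer = optimizer,
                 checkpoint_dir = checkpoint_dir, window = window),
            class = "train_config")
}

# fresh optimizer state shaped like the model's parameters
init_opt_state <- function(model) {
  lapply(model$layers, function(l) {
    list(mW = matrix(0, nrow(l$W), ncol(l$W)), vW = matrix(0, nrow(l$W), ncol(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
}

apply_update <- function(model, grads, opt, config, t) {
  lr <- config$learning_rate
  if (config$optimizer == "sgd") {
    for (l in seq_along(model$layers)) {
      model$layers[[l]]$W <- model$layers[[l]]$W - lr * grads[[l]]$dw
      model$layers[[l]]$b <- model$layers[[l]]$b - lr * grads[[l]]$db
    }
    return(list(model = model, opt = opt))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(model$layers)) {
    g <- grads[[l]]
    opt[[l]]$mW <- b1 * opt[[l]]$mW + (1 - b1) * g$dw
    opt[[l]]$vW <- b2 * opt[[l]]$vW + (1 - b2) * g$dw^2
    opt[[l]]$mb <- b1 * opt[[l]]$mb + (1 - b1) * g$db
    opt[[l]]$vb <- b2 * opt[[l]]$vb + (1 - b2) * g$db^2
    model$layers[[l]]$W <- model$layers[[l]]$W -
      lr * (opt[[l]]$mW / c1) / (sqrt(opt[[l]]$vW / c2) + eps)
    model$layers[[l]]$b <- model$layers[[l]]$b -
      lr * (opt[[l]]$mb / c1) / (sqrt(opt[[l]]$vb / c2) + eps)
  }
  list(model = model, opt = opt)
}

#' Train the recursive model on paired patches
#'
#' Stochastic gradient training of the shared parameters against the joint
#' pixel + perceptual loss on the final recursion stage's output. Batches
#' are drawn with a per-iteration seed derived from `config$seed` and the
#' global iteration number, so a run is bit-reproducible and a resumed run
#' continues the identical batch sequence.
#'
#' @param model a [build_model()] result.
#' @param patches patch tibble from [extract_patches()] (HU matrices).
#' @param config a [train_config()].
#' @param extractor a [feature_extractor()] for the perceptual term; built
#'   from `config$seed` when `NULL` and the perceptual weight is positive.
#' @return list with `model` (trained, iteration counter advanced) and
#'   `log`, a tibble with per-iteration `iteration`, `joint`, `mse`,
#'   `perceptual`, `checkpoint` (path or `NA`) and `time` stamps.
#' @export
train_model <- function(model, patches, config = train_config(),
                        extractor = NULL) {
  stopifnot(inherits(model, "red_model"), inherits(config, "train_config"))
  if (nrow(patches) == 0) stop("patch set is empty")
  d <- dim(patches$noisy[[1]])
  if (d[1] != config$patch_size || d[2] != config$patch_size) {
    stop("patches do not match config$patch_size = ", config$patch_size)
  }
  if (is.null(extractor) && config$perceptual_weight > 0) {
    extractor <- feature_extractor(seed = config$seed)
  }
  noisy <- lapply(patches$noisy, normalize_hu, window = config$window)
  clean <- lapply(patches$clean, normalize_hu, window = config$window)

  opt <- model$opt_state %||% init_opt_state(model)
  start <- model$iteration
  if (start >= config$max_iterations) {
    stop("model iteration ", start, " already at max_iterations")
  }
  iters <- (start + 1L):config$max_iterations
  log <- vector("list", length(iters))
  for (idx in seq_along(iters)) {
    t <- iters[idx]
    batch <- withr::with_seed(batch_seed(config$seed, t),
                              sample.int(length(noisy), config$batch_size,
                                         replace = TRUE))
    acc <- NULL
    mse_v <- per_v <- joint_v <- 0
    for (i in batch) {
      res <- recursive_forward_backward(model, noisy[[i]], function(O) {
        joint_loss_grad(O, clean[[i]], extractor, config$perceptual_weight)
      })
      acc <- if (is.null(acc)) res$grads else
        mapply(function(a, b) list(dw = a$dw + b$dw, db = a$db + b$db),
               acc, res$grads, SIMPLIFY = FALSE)
      mse_v <- mse_v + res$loss$mse_term
      per_v <- per_v + res$loss$perceptual_term
      joint_v <- joint_v + res$loss$joint
    }
    nb <- length(batch)
    acc <- lapply(acc, function(g) list(dw = g$dw / nb, db = g$db / nb))
    mse_v <- mse_v / nb; per_v <- per_v / nb; joint_v <- joint_v / nb
    if (!is.finite(joint_v)) {
      stop("non-finite loss at iteration ", t,
           " (mse = ", mse_v, ", perceptual = ", per_v, "); aborting")
    }
    upd <- apply_update(model, acc, opt, config, t)
    model <- upd$model; opt <- upd$opt
    model$iteration <- t

    ckpt <- NA_character_
    if (!is.null(config$checkpoint_dir) && t %% config$checkpoint_every == 0) {
      model$opt_state <- opt
      ckpt <- file.path(config$checkpoint_dir,
                        sprintf("checkpoint_%06d.rds", t))
      save_checkpoint(model, ckpt, config = config)
    }
    log[[idx]] <- tibble::tibble(iteration = t, joint = joint_v, mse = mse_v,
                                 perceptual = per_v, checkpoint = ckpt,
                                 time = Sys.time())
  }
  model$opt_state <- opt
  log <- dplyr::bind_rows(log)
  structure(list(model = model, log = log), class = "train_result")
}

# per-iteration batch seed, kept well below 2^31
batch_seed <- function(seed, t) {
  (as.integer(seed) %% 100000L) * 20011L + (t %% 20011L)
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d iterations, final joint loss %.6g\n",
              x$model$iteration, x$log$joint[nrow(x$log)]))
  invisible(x)
}

#' Save and load model checkpoints
#'
#' A checkpoint stores the model configuration, recursion count, seed,
#' iteration counter, optimizer state and all parameter tensors, plus the
#' training configuration when written from [train_model()]. Loading a
#' corrupt or non-checkpoint file raises an explicit error without partial
#' state.
#'
#' @param model a `red_model`.
#' @param path file path (`.rds`).
#' @param config optional `train_config` stored alongside.
#' @return `load_checkpoint()` returns a list with `model` and `config`.
#' @export
save_checkpoint <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "red_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(format = "redct-checkpoint", version = 1L, model = model,
               config = config), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("checkpoint at '", path, "' is unreadable or corrupt: ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "redct-checkpoint") ||
      !inherits(obj$model, "red_model")) {
    stop("file at '", path, "' is not a valid checkpoint", call. = FALSE)
  }
  obj[c("model", "config")]
}

#' Resume training from a checkpoint
#'
#' Continues iteration numbering, batch sequence, optimizer state and
#' checkpoint cadence exactly where the stored run stopped; a run of N
#' iterations is identical to N/2 iterations plus a resumed N/2.
#'
#' @param checkpoint_path path written by [train_model()]/[save_checkpoint()].
#' @param patches patch tibble (must match the stored patch size).
#' @param config a [train_config()]; must agree with the stored one on every
#'   field except `checkpoint_dir` and `max_iterations`.
#' @inheritParams train_model
#' @return as [train_model()].
#' @export
resume_training <- function(checkpoint_path, patches, config,
                            extractor = NULL) {
  ck <- load_checkpoint(checkpoint_path)
  if (!is.null(ck$config)) {
    fields <- setdiff(names(unclass(ck$config)),
                      c("checkpoint_dir", "max_iterations"))
    for (f in fields) {
      if (!identical(unclass(ck$config)[[f]], unclass(config)[[f]])) {
        stop("config field '", f, "' differs from the checkpointed run")
      }
    }
  }
  train_model(ck$model, patches, config, extractor = extractor)
}
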