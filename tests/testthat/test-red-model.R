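test_that("convolution kernels match brute-force oracles", {
  set.seed(1)
  k <- 3
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  W <- matrix(rnorm(k * k * 2 * 3), k * k * 2, 3)
  b <- rnorm(3)
  y <- redct:::cpp_conv_fwd(x, W, b)
  oracle <- array(0, c(5, 5, 3))
  for (co in 1:3) for (i in 1:5) for (j in 1:5) {
    s <- b[co]
    for (ci in 1:2) for (di in 0:2) for (dj in 0:2) {
      s <- s + x[i + di, j + dj, ci] * W[1 + di + k * dj + k * k * (ci - 1), co]
    }
    oracle[i, j, co] <- s
  }
  expect_equal(y, oracle, tolerance = 1e-12)

  xt <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  Wt <- matrix(rnorm(3 * k * k * 2), 3, k * k * 2)
  bt <- rnorm(2)
  yt <- redct:::cpp_tconv_fwd(xt, Wt, bt)
  oracle_t <- array(0, c(7, 7, 2))
  for (co in 1:2) oracle_t[, , co] <- bt[co]
  for (ci in 1:3) for (i in 1:5) for (j in 1:5) {
    for (di in 0:2) for (dj in 0:2) for (co in 1:2) {
      oracle_t[i + di, j + dj, co] <- oracle_t[i + di, j + dj, co] +
        xt[i, j, ci] * Wt[ci, 1 + di + k * dj + k * k * (co - 1)]
    }
  }
  expect_equal(yt, oracle_t, tolerance = 1e-12)
})

test_that("default architecture has 8 layers with 64/1 kernels", {
  model <- build_model(red_config(), seed = 1)
  expect_length(model$layers, 8)
  plan <- redct:::layer_plan(model$config)
  expect_equal(vapply(plan, `[[`, numeric(1), "cout"),
               c(rep(64, 7), 1))
  expect_equal(plan[[1]]$cin, 2)
  expect_equal(vapply(plan, `[[`, character(1), "type"),
               c(rep("conv", 4), rep("tconv", 4)))
})

test_that("weights are Gaussian(0, 0.01) and biases zero", {
  model <- build_model(red_config(), seed = 42)
  w <- unlist(lapply(model$layers, function(l) as.vector(l$W)))
  n <- length(w)
  expect_lt(abs(mean(w)), 3 * 0.01 / sqrt(n))
  expect_lt(abs(sd(w) - 0.01), 3 * 0.01 / sqrt(2 * n))
  expect_true(all(unlist(lapply(model$layers, `[[`, "b")) == 0))
})

test_that("model building is deterministic in the seed", {
  expect_identical(build_model(red_config(), seed = 7),
                   build_model(red_config(), seed = 7))
  expect_false(identical(build_model(red_config(), seed = 7)$layers,
                         build_model(red_config(), seed = 8)$layers))
})

test_that("config validation rejects odd layer counts and even kernels", {
  expect_error(red_config(n_layers = 7), "even")
  expect_error(red_config(n_layers = 2), "even")
  expect_error(red_config(kernel_size = 4), "odd")
})

test_that("shallow forward preserves shape and shrinks to the bottleneck", {
  model <- build_model(red_config(), seed = 1)
  X <- matrix(runif(48 * 48), 48, 48)
  out <- forward_shallow(model, X)
  expect_equal(dim(out), c(48, 48))
  # encoder bottleneck: 48 - 4*(3-1) = 40
  I <- array(c(X, X), dim = c(48, 48, 2))
  fw <- redct:::shallow_forward(model$layers, model$config, I, keep = TRUE)
  expect_equal(dim(fw$cache$act[[5]]), c(40, 40, 64))
  # shape preservation holds at other sizes too
  for (n in c(9, 17, 33)) {
    Xn <- matrix(runif(n * n), n, n)
    expect_equal(dim(forward_shallow(model, Xn)), c(n, n))
  }
  expect_error(forward_shallow(model, matrix(0, 8, 8)), "too small")
})

test_that("zero-weight model is the identity at every recursion stage", {
  model <- zero_weights(build_model(red_config(), seed = 1, S = 4))
  X <- matrix(runif(20 * 20), 20, 20)
  expect_equal(forward_shallow(model, X), X)
  fr <- forward_recursive(model, X)
  for (s in seq_len(model$S)) expect_equal(fr$trace$outputs[[s]], X)
})

test_that("recursion trace satisfies the cascade contract", {
  model <- build_model(red_config(), seed = 3, S = 5)
  X <- matrix(runif(16 * 16), 16, 16)
  fr <- forward_recursive(model, X)
  tr <- fr$trace
  expect_identical(tr$inputs[[1]][, , 1], X)
  expect_identical(tr$inputs[[1]][, , 2], X)
  for (s in 1:4) {
    expect_identical(tr$inputs[[s + 1]][, , 1], tr$outputs[[s]])
    expect_identical(tr$inputs[[s + 1]][, , 2], X)
  }
  expect_identical(fr$output, tr$outputs[[5]])
  expect_true(all(vapply(tr$outputs, function(o) all(dim(o) == dim(X)),
                         logical(1))))
  expect_error(forward_recursive(model, X, S = 0), "S")
})

test_that("parameters are shared across recursions", {
  cfg <- red_config()
  models <- lapply(c(1, 3, 5), function(S) build_model(cfg, seed = 5, S = S))
  expect_equal(n_parameters(models[[1]]), n_parameters(models[[3]]))
  payloads <- lapply(models, parameter_payload)
  expect_identical(payloads[[1]], payloads[[2]])
  expect_identical(payloads[[2]], payloads[[3]])
})

test_that("forward passes are reproducible bit-for-bit", {
  model <- build_model(red_config(), seed = 11, S = 2)
  X <- matrix(runif(16 * 16), 16, 16)
  expect_identical(forward_recursive(model, X)$output,
                   forward_recursive(model, X)$output)
})

test_that("complexity matches direct evaluation of the layer sum", {
  # single layer: n0 = 1, f = 3, n1 = 64 -> 576
  cfg1 <- red_config(n_layers = 4, kernels_per_hidden_layer = 64,
                     input_channels = 1)
  plan1 <- redct:::layer_plan(cfg1)
  expect_equal(plan1[[1]]$cin * 9 * plan1[[1]]$cout, 576)

  # default config vs an independent hand sum over the layer list
  cfg <- red_config()
  hand <- 2 * 9 * 64 + 6 * (64 * 9 * 64) + 64 * 9 * 1
  expect_equal(model_complexity(cfg, 1), hand)
  expect_equal(model_complexity(cfg, 5), 5 * hand)

  # doubling hidden kernels multiplies hidden-to-hidden terms by 4
  c1 <- red_config(kernels_per_hidden_layer = 64)
  c2 <- red_config(kernels_per_hidden_layer = 128)
  hidden1 <- 6 * 64 * 9 * 64
  hidden2 <- 6 * 128 * 9 * 128
  expect_equal(hidden2, 4 * hidden1)
  expect_equal(model_complexity(c2, 1) - (2 * 9 * 128 + 128 * 9),
               4 * (model_complexity(c1, 1) - (2 * 9 * 64 + 64 * 9)))
})

test_that("complexity agrees with a brute-force oracle for random configs", {
  set.seed(99)
  for (rep in 1:20) {
    nl <- 2 * sample(2:5, 1)
    K <- sample(c(4, 8, 16, 32), 1)
    ic <- sample(1:3, 1)
    ks <- sample(c(3, 5), 1)
    S <- sample(1:6, 1)
    cfg <- red_config(n_layers = nl, kernels_per_hidden_layer = K,
                      input_channels = ic, kernel_size = ks)
    chans <- c(ic, rep(K, nl - 1), 1)
    oracle <- 0
    for (l in seq_len(nl)) oracle <- oracle + chans[l] * ks^2 * chans[l + 1]
    expect_equal(model_complexity(cfg, S), oracle * S)
  }
})

test_that("denoising maps HU in and out of the network domain", {
  model <- zero_weights(build_model(red_config(), seed = 1, S = 2))
  img <- water_disc_image(32)
  den <- denoise_image(model, img)
  expect_s3_class(den, "ct_image")
  expect_equal(unclass(den), unclass(img), tolerance = 1e-10)
})

test_that("model tidiers summarize layers and totals", {
  model <- build_model(red_config(), seed = 1, S = 5)
  td <- tidy(model)
  expect_equal(nrow(td), 8)
  gl <- glance(model)
  expect_equal(gl$n_parameters, n_parameters(model))
  expect_equal(gl$complexity, model_complexity(model$config, 5))
})
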