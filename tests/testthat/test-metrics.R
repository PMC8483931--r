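# independent brute-force metric oracles, explicit loops over quantized pixels
oracle_psnr <- function(qi, qk) {
  s <- 0
  for (i in seq_len(nrow(qi))) for (j in seq_len(ncol(qi))) {
    s <- s + (qi[i, j] - qk[i, j])^2
  }
  if (s == 0) return(Inf)
  20 * log10(255 / sqrt(s / (nrow(qi) * ncol(qi))))
}

oracle_ssim <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- 0; vy <- 0; cxy <- 0
  for (i in seq_along(x)) {
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
    cxy <- cxy + (x[i] - mx) * (y[i] - my)
  }
  vx <- vx / n; vy <- vy / n; cxy <- cxy / n
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

oracle_rmse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] / 255 - y[i] / 255)^2
  sqrt(s / length(x))
}

random_hu_pair <- function(seed, n = 8) {
  withr::with_seed(seed, list(
    a = ct_image(matrix(runif(n * n, -1000, 2000), n, n)),
    b = ct_image(matrix(runif(n * n, -1000, 2000), n, n))))
}

test_that("psnr satisfies its boundary cases", {
  a <- ct_image(matrix(c(0, 100, 200, 300), 2, 2))
  expect_identical(psnr(a, a), Inf)
  lo <- ct_image(matrix(-1000, 4, 4))
  hi <- ct_image(matrix(2000, 4, 4))
  expect_equal(psnr(lo, hi), 0)   # 20*log10(255/255)
  expect_error(psnr(lo, ct_image(matrix(0, 2, 2))), "shape")
})

test_that("ssim is symmetric, 1 at identity, and matches closed forms", {
  p <- random_hu_pair(1)
  expect_identical(ssim(p$a, p$a), 1)
  expect_equal(ssim(p$a, p$b), ssim(p$b, p$a))
  # constant images: covariance and variances vanish
  ca <- ct_image(matrix(200, 5, 5))    # quantizes to 102
  cb <- ct_image(matrix(800, 5, 5))    # quantizes to 153
  c1 <- (0.01 * 255)^2
  qa <- 102; qb <- 153
  expect_equal(ssim(ca, cb), (2 * qa * qb + c1) / (qa^2 + qb^2 + c1),
               tolerance = 1e-12)
})

test_that("rmse satisfies identity and exact-offset cases", {
  a <- ct_image(matrix(0, 6, 6))
  expect_identical(rmse(a, a), 0)
  # +600 HU over the 3000 HU window is exactly 51/255 in unit range
  b <- ct_image(matrix(600, 6, 6))
  expect_equal(rmse(a, b), 51 / 255, tolerance = 1e-12)
})

test_that("metrics match brute-force oracles on 50 random pairs", {
  for (s in 1:50) {
    p <- random_hu_pair(s)
    qa <- quantize_hu(p$a); qb <- quantize_hu(p$b)
    expect_equal(psnr(p$a, p$b), oracle_psnr(qa, qb), tolerance = 1e-9)
    expect_equal(ssim(p$a, p$b), oracle_ssim(as.vector(qa), as.vector(qb)),
                 tolerance = 1e-9)
    expect_equal(rmse(p$a, p$b), oracle_rmse(as.vector(qa), as.vector(qb)),
                 tolerance = 1e-9)
  }
})

test_that("psnr decreases monotonically with added noise", {
  img <- water_disc_image(32)
  mean_psnr <- vapply(c(5, 10, 20, 40), function(s) {
    mean(vapply(1:20, function(seed) {
      noise <- withr::with_seed(seed * 100 + s,
                                matrix(rnorm(1024, 0, s), 32, 32))
      psnr(img, ct_image(unclass(img) + noise))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("aggregation reproduces means, display rounding and differences", {
  path <- system.file("extdata", "published_benchmark_metrics.csv",
                      package = "redct")
  rep <- aggregate_metrics(read.csv(path))
  avg <- rep$averages
  expect_equal(avg$display_psnr[avg$method == "ldct"], 25.791)
  expect_equal(avg$display_psnr[avg$method == "proposed"], 30.784)
  # single record aggregates to itself
  one <- metrics_record(water_disc_image(32), water_disc_image(32), "x", "m")
  expect_warning(r1 <- aggregate_metrics(one), NA)
  expect_equal(r1$averages$mean_ssim, 1)
  # constant records average to the constant
  recs <- tibble::tibble(image_id = letters[1:4], method = "m",
                         psnr_db = 31.5, ssim = 0.9)
  expect_equal(aggregate_metrics(recs)$averages$mean_psnr, 31.5)
  expect_error(aggregate_metrics(recs[0, ]), "no metric records")
})

test_that("display rounding is half-up", {
  expect_equal(redct:::round_half_up(0.0005, 3), 0.001)
  expect_equal(redct:::round_half_up(2.3445, 3), 2.345)
  expect_equal(redct:::round_half_up(-0.0004, 3), 0)
})

test_that("evaluate_pipeline scores identity denoising as the raw input", {
  model <- zero_weights(build_model(red_config(), seed = 1, S = 2))
  pairs <- tibble::tibble(
    image_id = c("p1", "p2"),
    ndct = list(water_disc_image(32), water_disc_image(32, radius = 0.2)),
    ldct = list(water_disc_image(32, noise_sd = 20, seed = 1),
                water_disc_image(32, noise_sd = 20, seed = 2)))
  rep <- evaluate_pipeline(model, pairs)
  rows <- rep$rows
  for (id in c("p1", "p2")) {
    ld <- rows[rows$image_id == id & rows$method == "ldct", ]
    de <- rows[rows$image_id == id & rows$method == "denoised", ]
    expect_equal(de$psnr_db, ld$psnr_db)
    expect_equal(de$ssim, ld$ssim)
  }
})

test_that("evaluate_pipeline is deterministic and optimization adds rows", {
  model <- zero_weights(build_model(red_config(), seed = 1, S = 2))
  pairs <- tibble::tibble(
    image_id = "p1",
    ndct = list(water_disc_image(32)),
    ldct = list(water_disc_image(32, noise_sd = 15, seed = 3)))
  r1 <- evaluate_pipeline(model, pairs, seed = 2)
  r2 <- evaluate_pipeline(model, pairs, seed = 2)
  expect_identical(r1$rows, r2$rows)
  r3 <- evaluate_pipeline(model, pairs, with_optimization = TRUE, seed = 2)
  expect_setequal(unique(r3$rows$method), c("ldct", "denoised",
                                            "denoised_opt"))
  # base rows unchanged by toggling the optimization flag
  expect_identical(r3$rows[r3$rows$method != "denoised_opt", ], r1$rows)
  # unpaired shapes are rejected
  bad <- pairs; bad$ldct <- list(water_disc_image(48))
  expect_error(evaluate_pipeline(model, bad), "unpaired")
})

test_that("report tidiers expose rows and averages", {
  path <- system.file("extdata", "published_benchmark_metrics.csv",
                      package = "redct")
  rep <- aggregate_metrics(read.csv(path))
  expect_equal(nrow(tidy(rep)), 36)
  expect_equal(nrow(glance(rep)), 4)
})
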