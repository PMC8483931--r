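test_that("trimodal image segments to exact ground-truth masks", {
  img <- withr::with_seed(1, ct_image(
    matrix(sample(c(-1000, 0, 1000), 1024, replace = TRUE), 32, 32)))
  seg <- segment_tissues(img)
  expect_true(all((seg$labels == "air") == (unclass(img) == -1000)))
  expect_true(all((seg$labels == "water") == (unclass(img) == 0)))
  expect_true(all((seg$labels == "bone") == (unclass(img) == 1000)))
  expect_identical(seg$water_mask, (seg$labels == "water") + 0)
})

test_that("labels always partition the image and the bone floor holds", {
  for (s in 1:5) {
    img <- generate_phantom(random_phantom_spec(48, seed = s))
    noisy <- ct_image(unclass(img) +
                        withr::with_seed(s, matrix(rnorm(48 * 48, 0, 15),
                                                   48, 48)))
    seg <- segment_tissues(noisy, seed = s)
    counts <- table(factor(seg$labels, levels = c("air", "water", "bone")))
    expect_equal(sum(counts), 48 * 48)
    expect_gte(seg$thresholds[["water_bone"]], 320)
  }
})

test_that("constant images raise a degenerate-clustering error", {
  flat <- ct_image(matrix(0, 32, 32))
  expect_error(segment_tissues(flat), "degenerate clustering.*flat")
})

test_that("transition weights implement the clipped distance transform", {
  expect_equal(formals(transition_weights)$L, 5)
  # all-water mask: no zero pixel anywhere, clip applies everywhere
  seg_all <- list(water_mask = matrix(1, 8, 8))
  w <- transition_weights(seg_all, L = 5)
  expect_true(all(w$D == 5))
  expect_error(transition_weights(seg_all, L = 0), "L")
})

test_that("distance weights match a brute-force all-pairs oracle", {
  mask <- matrix(0, 16, 16)
  mask[4:12, 5:13] <- 1
  mask[8, 9] <- 0   # interior hole
  w <- transition_weights(list(water_mask = mask), L = 5)
  zeros <- which(mask == 0, arr.ind = TRUE)
  for (i in 1:16) {
    for (j in 1:16) {
      if (mask[i, j] == 0) {
        expect_identical(w$D[i, j], 0)
      } else {
        d <- min(sqrt((zeros[, 1] - i)^2 + (zeros[, 2] - j)^2))
        expect_equal(w$D[i, j], min(d, 5), tolerance = 1e-9)
      }
    }
  }
  # water pixel 4-adjacent to the interior hole has D = 1, its diagonal
  # neighbor sqrt(2)
  expect_equal(w$D[9, 9], 1)
  expect_equal(w$D[9, 10], sqrt(2), tolerance = 1e-9)
  expect_equal(w$D[4, 5], 1)   # edge-adjacent border pixel
})

test_that("weighted water mean matches uniform, single-support and loops", {
  img <- ct_image(matrix(seq(-100, 140, by = 10), 5, 5))
  # uniform weights over a water subset -> plain mean of those pixels
  D <- matrix(0, 5, 5); D[2:4, 2:4] <- 5
  wm <- weighted_water_mean(img, list(D = D, L = 5))
  expect_equal(wm, mean(unclass(img)[2:4, 2:4]))
  # single supported pixel -> its value
  D1 <- matrix(0, 5, 5); D1[3, 3] <- 2
  expect_equal(weighted_water_mean(img, list(D = D1, L = 5)),
               unclass(img)[3, 3])
  # brute-force loop on an irregular weight map
  D2 <- withr::with_seed(2, matrix(runif(25, 0, 5) *
                                     rbinom(25, 1, 0.6), 5, 5))
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:5) {
    num <- num + D2[i, j] * unclass(img)[i, j]
    den <- den + D2[i, j]
  }
  expect_equal(weighted_water_mean(img, list(D = D2, L = 5)), num / den,
               tolerance = 1e-12)
  expect_error(weighted_water_mean(img, list(D = matrix(0, 5, 5), L = 5)),
               "no water")
})

test_that("prior image blends linearly between pixel and water mean", {
  img <- ct_image(matrix(seq(-100, 140, by = 10), 5, 5))
  D <- matrix(0, 5, 5)
  D[1, 1] <- 5      # full blend
  D[2, 2] <- 2.5    # midpoint
  wm <- 40
  out <- unclass(prior_image(img, list(D = D, L = 5), wm))
  expect_identical(out[1, 1], wm)
  expect_equal(out[2, 2], (wm + unclass(img)[2, 2]) / 2)
  expect_identical(out[3, 3], unclass(img)[3, 3])   # D = 0 untouched
})

test_that("optimize flattens noisy uniform water and spares everything else", {
  noisy <- water_disc_image(64, noise_sd = 20, seed = 4)
  out <- optimize_tissues(noisy)
  D <- out$weights$D
  interior <- D == out$weights$L
  expect_gt(sum(interior), 0)
  expect_equal(sd(unclass(out$image)[interior]), 0)
  expect_true(all(unclass(out$image)[interior] == out$water_mean))
  band <- D > 0 & D < out$weights$L
  expect_lt(sd(unclass(out$image)[band]), sd(unclass(noisy)[band]))
  expect_lt(sd(unclass(out$image)[band]), 20)
  expect_identical(unclass(out$image)[D == 0], unclass(noisy)[D == 0])
})

test_that("optimized pixels stay between the pixel value and the water mean", {
  noisy <- water_disc_image(48, noise_sd = 25, seed = 6)
  out <- optimize_tissues(noisy)
  lo <- pmin(unclass(noisy), out$water_mean)
  hi <- pmax(unclass(noisy), out$water_mean)
  expect_true(all(unclass(out$image) >= lo - 1e-9 &
                    unclass(out$image) <= hi + 1e-9))
})

test_that("optimize leaves an already-flat water region unchanged", {
  # water region constant at 0 HU, plus a bone insert for three HU classes
  flat <- generate_phantom(phantom_spec(64, list(
    ellipse(0.5, 0.5, 0.3, 0.3, class = "water"),
    ellipse(0.2, 0.2, 0.06, 0.06, class = "bone"))))
  once <- optimize_tissues(flat)
  expect_identical(unclass(once$image), unclass(flat))
  twice <- optimize_tissues(once$image)
  expect_identical(unclass(twice$image), unclass(once$image))
})

test_that("images without water pass through unchanged with a warning", {
  # air background with a bone insert only: the middle cluster sits above
  # the 320 HU bone floor, so no pixel is water-equivalent
  img <- generate_phantom(phantom_spec(32, list(
    ellipse(0.5, 0.5, 0.25, 0.25, class = "bone"))))
  noisy <- ct_image(unclass(img) +
                      withr::with_seed(5, matrix(rnorm(1024, 0, 10), 32, 32)))
  expect_warning(out <- optimize_tissues(noisy), "no water")
  expect_identical(unclass(out$image), unclass(noisy))
  expect_true(is.na(out$water_mean))
  expect_gte(out$segmentation$thresholds[["water_bone"]], 320)
})

test_that("optimize equals manual chaining of its stages", {
  noisy <- water_disc_image(48, noise_sd = 10, seed = 12)
  out <- optimize_tissues(noisy, L = 5, seed = 3)
  seg <- segment_tissues(noisy, seed = 3)
  w <- transition_weights(seg, L = 5)
  wm <- weighted_water_mean(noisy, w)
  manual <- prior_image(noisy, w, wm)
  expect_identical(unclass(out$image), unclass(manual))
  expect_equal(out$water_mean, wm)
})
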