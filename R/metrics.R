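#' Quantize HU images to 8-bit under a shared display window
#'
#' All fidelity metrics are defined on 8-bit images (peak value 255), so HU
#' images are first clamped to a display window (default \[-1000, 2000\] HU)
#' and linearly mapped to integers 0..255.
#'
#' @param image a [ct_image()] or numeric matrix in HU.
#' @param window length-2 HU display window.
#' @return integer-valued matrix in 0..255.
#' @export
quantize_hu <- function(image, window = c(-1000, 2000)) {
  m <- hu_matrix(as_ct_image(image))
  m <- pmin(pmax(m, window[1]), window[2])
  round((m - window[1]) / (window[2] - window[1]) * 255)
}

assert_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images differ in shape")
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(255 / RMSE)` on the 8-bit quantizations of the two images
#' under a shared display window. Identical images give `Inf` (the
#' "infinite" sentinel for zero error).
#'
#' @param reference,test [ct_image()]s or matrices of identical shape.
#' @param window HU display window used for quantization.
#' @return PSNR in dB.
#' @examples
#' a <- ct_image(matrix(c(0, 100, 200, 300), 2, 2))
#' psnr(a, a)
#' @export
psnr <- function(reference, test, window = c(-1000, 2000)) {
  qi <- quantize_hu(reference, window)
  qk <- quantize_hu(test, window)
  assert_same_shape(qi, qk)
  mse <- mean((qi - qk)^2)
  if (mse == 0) return(Inf)
  20 * log10(255 / sqrt(mse))
}

#' Structural similarity (global-statistics form)
#'
#' The single-window SSIM computed from whole-image means, variances and
#' covariance of the 8-bit quantizations:
#' `((2*mu_x*mu_y + c1) * (2*cov + c2)) / ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))`
#' with the standard constants `c1 = (0.01*255)^2`, `c2 = (0.03*255)^2`.
#' A sliding-window variant (11 px window, Gaussian-free uniform mean) is
#' available via `windowed = TRUE` but is not the default.
#'
#' @inheritParams psnr
#' @param a,b [ct_image()]s or matrices of identical shape.
#' @param windowed use an 11 px sliding window instead of global statistics.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b, window = c(-1000, 2000), windowed = FALSE) {
  qa <- quantize_hu(a, window)
  qb <- quantize_hu(b, window)
  assert_same_shape(qa, qb)
  c1 <- (0.01 * 255)^2
  c2 <- (0.03 * 255)^2
  stat <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  if (!windowed) return(stat(qa, qb))
  w <- 11L
  if (nrow(qa) < w || ncol(qa) < w) stop("image smaller than the 11 px window")
  vals <- c()
  for (i in seq_len(nrow(qa) - w + 1L)) {
    for (j in seq_len(ncol(qa) - w + 1L)) {
      vals <- c(vals, stat(qa[i:(i + w - 1L), j:(j + w - 1L)],
                           qb[i:(i + w - 1L), j:(j + w - 1L)]))
    }
  }
  mean(vals)
}

#' Root-mean-square error on unit-range images
#'
#' RMSE of the 8-bit quantizations rescaled to \[0, 1\], so a uniform offset
#' of c maps to an RMSE of |c|.
#'
#' @inheritParams ssim
#' @return non-negative scalar.
#' @export
rmse <- function(a, b, window = c(-1000, 2000)) {
  qa <- quantize_hu(a, window) / 255
  qb <- quantize_hu(b, window) / 255
  assert_same_shape(qa, qb)
  sqrt(mean((qa - qb)^2))
}

#' Per-image metrics record
#'
#' Computes PSNR, SSIM and RMSE for one image pair under a shared display
#' window and returns a one-row tibble suitable for [aggregate_metrics()].
#'
#' @inheritParams psnr
#' @param image_id label identifying the image.
#' @param method label identifying the denoising method.
#' @return one-row tibble: `image_id`, `method`, `psnr_db`, `ssim`, `rmse`.
#' @export
metrics_record <- function(reference, test, image_id, method,
                           window = c(-1000, 2000)) {
  tibble::tibble(image_id = as.character(image_id),
                 method = as.character(method),
                 psnr_db = psnr(reference, test, window),
                 ssim = ssim(reference, test, window),
                 rmse = rmse(reference, test, window))
}

# round half up at d decimals (display rounding for report tables)
round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

#' Aggregate per-image metric records into a report table
#'
#' Computes per-method arithmetic means of PSNR and SSIM (unrounded, with
#' half-up display rounding at `decimals`) and all pairwise mean-PSNR /
#' mean-SSIM differences between methods.
#'
#' @param records tibble with columns `image_id`, `method`, `psnr_db`,
#'   `ssim` (and optionally `rmse`), e.g. rows from [metrics_record()].
#' @param decimals display decimals, half-up (default 3).
#' @return a `redct_report`: list with `rows` (the input records),
#'   `averages` (per-method means plus display-rounded columns),
#'   `differences` (pairwise mean differences) and `decimals`.
#' @examples
#' path <- system.file("extdata", "published_benchmark_metrics.csv",
#'                     package = "redct")
#' rep <- aggregate_metrics(read.csv(path))
#' rep$averages
#' @export
aggregate_metrics <- function(records, decimals = 3) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no metric records to aggregate")
  stopifnot(all(c("image_id", "method", "psnr_db", "ssim") %in%
                  names(records)))
  averages <- records |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_psnr = mean(.data$psnr_db),
                     mean_ssim = mean(.data$ssim), .groups = "drop") |>
    dplyr::mutate(display_psnr = round_half_up(.data$mean_psnr, decimals),
                  display_ssim = round_half_up(.data$mean_ssim, decimals))
  methods <- averages$method
  pairs <- expand.grid(method_a = methods, method_b = methods,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$method_a != pairs$method_b, ]
  differences <- tibble::as_tibble(pairs) |>
    dplyr::mutate(
      psnr_diff = averages$mean_psnr[match(.data$method_a, methods)] -
        averages$mean_psnr[match(.data$method_b, methods)],
      ssim_diff = averages$mean_ssim[match(.data$method_a, methods)] -
        averages$mean_ssim[match(.data$method_b, methods)])
  structure(list(rows = records, averages = averages,
                 differences = differences, decimals = decimals),
            class = "redct_report")
}

#' @export
print.redct_report <- function(x, ...) {
  cat(sprintf("<redct_report> %d records, %d methods\n",
              nrow(x$rows), nrow(x$averages)))
  print(as.data.frame(x$averages), row.names = FALSE)
  invisible(x)
}

#' Denoise and score a paired image set end to end
#'
#' For every normal-dose/low-dose pair: denoise the low-dose image with the
#' recursive model, optionally apply the water-equivalent tissue
#' optimization, and score the raw low-dose input, the network output and
#' (if enabled) the optimized output against the normal-dose reference.
#'
#' @param model a `red_model`.
#' @param pairs tibble with list-columns `ndct` and `ldct` of [ct_image()]s
#'   (or HU matrices) and an `image_id` column.
#' @param with_optimization apply [optimize_tissues()] after the network?
#' @param seed integer seed (drives the tissue segmentation).
#' @param window HU display window shared by normalization and metrics.
#' @param L transition width for the optimization step.
#' @return a `redct_report` (see [aggregate_metrics()]).
#' @export
evaluate_pipeline <- function(model, pairs, with_optimization = FALSE,
                              seed = 1L, window = c(-1000, 2000), L = 5) {
  stopifnot(all(c("ndct", "ldct", "image_id") %in% names(pairs)))
  if (nrow(pairs) == 0) stop("no image pairs to evaluate")
  rows <- purrr::pmap(pairs[c("ndct", "ldct", "image_id")],
                      function(ndct, ldct, image_id) {
    ndct <- as_ct_image(ndct); ldct <- as_ct_image(ldct)
    if (!all(dim(ndct) == dim(ldct))) {
      stop("unpaired inputs: image '", image_id, "' sizes differ")
    }
    den <- denoise_image(model, ldct, window = window)
    out <- list(metrics_record(ndct, ldct, image_id, "ldct", window),
                metrics_record(ndct, den, image_id, "denoised", window))
    if (with_optimization) {
      opt <- optimize_tissues(den, L = L, seed = seed)
      out[[3]] <- metrics_record(ndct, opt$image, image_id, "denoised_opt",
                                 window)
    }
    dplyr::bind_rows(out)
  })
  aggregate_metrics(dplyr::bind_rows(rows))
}
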