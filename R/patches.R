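#' Extract paired training patches from a noisy/clean image pair
#'
#' Samples `n_patches` offsets uniformly (with replacement) over all valid
#' positions and cuts the same window from both images, so every noisy patch
#' is pixel-aligned with its clean counterpart. The 48 px default follows the
#' training protocol the network was designed for.
#'
#' @param noisy,clean [ct_image()]s of identical dimensions.
#' @param patch_size square patch side in pixels (default 48).
#' @param n_patches number of pairs to draw.
#' @param seed integer seed.
#' @param source_index integer identifier of the source image pair, recorded
#'   per patch.
#' @return a tibble with one row per pair: list-columns `noisy` and `clean`
#'   (HU matrices), `source_index`, and the top-left `row`/`col` offsets.
#' @export
extract_patches <- function(noisy, clean, patch_size = 48, n_patches = 100,
                            seed = 1L, source_index = 1L) {
  noisy <- as_ct_image(noisy); clean <- as_ct_image(clean)
  if (!all(dim(noisy) == dim(clean))) stop("paired images must match in shape")
  if (patch_size > nrow(noisy) || patch_size > ncol(noisy)) {
    stop("patch_size exceeds image dimensions")
  }
  nm <- hu_matrix(noisy); cm <- hu_matrix(clean)
  max_r <- nrow(nm) - patch_size + 1L
  max_c <- ncol(nm) - patch_size + 1L
  offs <- withr::with_seed(as.integer(seed), {
    data.frame(row = sample.int(max_r, n_patches, replace = TRUE),
               col = sample.int(max_c, n_patches, replace = TRUE))
  })
  cut <- function(m, r, c) m[r:(r + patch_size - 1L), c:(c + patch_size - 1L)]
  tibble::tibble(
    noisy = purrr::map2(offs$row, offs$col, ~cut(nm, .x, .y)),
    clean = purrr::map2(offs$row, offs$col, ~cut(cm, .x, .y)),
    source_index = as.integer(source_index),
    row = offs$row,
    col = offs$col
  )
}
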