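#' Read and write CT images as PNG/TIFF with a JSON sidecar
#'
#' HU values are windowed to `window`, rescaled, and written as a grayscale
#' image; a sidecar JSON (`<path>.json`) records the window and pixel
#' spacing so reading inverts the mapping up to the format's quantization.
#' TIFF is written at 16 bits per sample (about 0.05 HU over the default
#' window); PNG is 8-bit (about 6 HU), adequate for display exports. Use
#' [write_ct_raw()] for lossless storage.
#'
#' @param image a [ct_image()].
#' @param path output file path.
#' @param window HU window stored in the sidecar (default `c(-1000, 2000)`).
#' @return the path, invisibly; readers return a [ct_image()].
#' @export
write_ct_png <- function(image, path, window = c(-1000, 2000)) {
  image <- as_ct_image(image)
  png::writePNG(windowed_unit(image, window), path)
  write_sidecar(path, image, window)
  invisible(path)
}

#' @rdname write_ct_png
#' @export
read_ct_png <- function(path) {
  arr <- png::readPNG(path)
  read_windowed(arr, path)
}

#' @rdname write_ct_png
#' @export
write_ct_tiff <- function(image, path, window = c(-1000, 2000)) {
  image <- as_ct_image(image)
  tiff::writeTIFF(windowed_unit(image, window), path, bits.per.sample = 16L)
  write_sidecar(path, image, window)
  invisible(path)
}

#' @rdname write_ct_png
#' @export
read_ct_tiff <- function(path) {
  arr <- tiff::readTIFF(path)
  read_windowed(arr, path)
}

windowed_unit <- function(image, window) {
  m <- pmin(pmax(hu_matrix(image), window[1]), window[2])
  (m - window[1]) / (window[2] - window[1])
}

write_sidecar <- function(path, image, window) {
  jsonlite::write_json(
    list(hu_window = window, pixel_spacing = pixel_spacing(image),
         shape = dim(image)),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
}

read_windowed <- function(arr, path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar JSON for '", path, "'")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  w <- meta$hu_window
  ct_image(arr * (w[2] - w[1]) + w[1], pixel_spacing = meta$pixel_spacing)
}

#' Raw array container for CT images
#'
#' Lossless storage: little-endian doubles in `<path>` plus a JSON header
#' (`<path>.json`) with shape, dtype and pixel spacing.
#'
#' @inheritParams write_ct_png
#' @export
write_ct_raw <- function(image, path) {
  image <- as_ct_image(image)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(hu_matrix(image)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(shape = dim(image), dtype = "float64", order = "column-major",
         pixel_spacing = pixel_spacing(image)),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_ct_raw
#' @export
read_ct_raw <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing header JSON for '", path, "'")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$shape), size = 8,
                  endian = "little")
  ct_image(matrix(vals, meta$shape[1], meta$shape[2]),
           pixel_spacing = meta$pixel_spacing)
}

#' Write a simulated paired dataset to disk
#'
#' Renders `n_phantoms` random phantoms, simulates a low-dose counterpart
#' for each, writes `*_ndct.raw` / `*_ldct.raw` pairs and a JSON manifest.
#' This is the programmatic core of the `redct simulate` command-line tool.
#'
#' @param out_dir output directory (created if needed).
#' @param n_phantoms number of pairs.
#' @param size phantom side length in pixels.
#' @param incident_photons dose parameter for the noise simulation.
#' @param seed integer master seed; pair i uses `seed + i`.
#' @param n_angles projection angles.
#' @return the manifest path, invisibly.
#' @export
write_simulated_pairs <- function(out_dir, n_phantoms = 4, size = 128,
                                  incident_photons = 1e5, seed = 1L,
                                  n_angles = 180) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", n_phantoms)
  for (i in seq_len(n_phantoms)) {
    s <- as.integer(seed) + i
    nd <- generate_phantom(random_phantom_spec(size, seed = s))
    ld <- simulate_low_dose(nd, incident_photons, seed = s,
                            n_angles = n_angles)
    ndp <- file.path(out_dir, sprintf("pair%03d_ndct.raw", i))
    ldp <- file.path(out_dir, sprintf("pair%03d_ldct.raw", i))
    write_ct_raw(nd, ndp)
    write_ct_raw(ld, ldp)
    entries[[i]] <- list(image_id = sprintf("pair%03d", i), ndct = ndp,
                         ldct = ldp, seed = s)
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(n_phantoms = n_phantoms, size = size,
         incident_photons = incident_photons, n_angles = n_angles,
         master_seed = as.integer(seed), pairs = entries),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a simulated-pairs manifest back into an evaluation tibble
#'
#' @param manifest path written by [write_simulated_pairs()].
#' @return tibble with `image_id`, `ndct`, `ldct` columns ready for
#'   [evaluate_pipeline()].
#' @export
read_simulated_pairs <- function(manifest) {
  meta <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  tibble::tibble(
    image_id = purrr::map_chr(meta$pairs, "image_id"),
    ndct = purrr::map(meta$pairs, ~read_ct_raw(.x$ndct)),
    ldct = purrr::map(meta$pairs, ~read_ct_raw(.x$ldct))
  )
}
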