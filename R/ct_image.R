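#' CT image in Hounsfield units
#'
#' A `ct_image` is a numeric matrix of Hounsfield-unit (HU) values with a
#' `pixel_spacing` attribute (mm per pixel). It is the universal currency of
#' the package: phantoms, reconstructions, network inputs/outputs and
#' tissue-optimized images are all `ct_image` objects. By CT convention air
#' is -1000 HU and water 0 HU.
#'
#' @param values numeric matrix of HU values; must be non-empty and finite.
#' @param pixel_spacing pixel size in mm (default 1).
#' @return a `ct_image` object.
#' @examples
#' img <- ct_image(matrix(0, 32, 32))
#' dim(img)
#' @export
ct_image <- function(values, pixel_spacing = 1) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("ct_image must be non-empty")
  if (!is.numeric(values)) stop("ct_image values must be numeric")
  if (!all(is.finite(values))) stop("ct_image values must all be finite")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0) {
    stop("pixel_spacing must be a single positive number")
  }
  structure(values, pixel_spacing = as.numeric(pixel_spacing),
            class = c("ct_image", "matrix", "array"))
}

#' @rdname ct_image
#' @param x object to coerce or test.
#' @export
as_ct_image <- function(x, pixel_spacing = NULL) {
  if (is_ct_image(x)) {
    if (!is.null(pixel_spacing)) attr(x, "pixel_spacing") <- pixel_spacing
    return(x)
  }
  ct_image(x, pixel_spacing %||% 1)
}

#' @rdname ct_image
#' @export
is_ct_image <- function(x) inherits(x, "ct_image")

#' @rdname ct_image
#' @export
pixel_spacing <- function(x) attr(x, "pixel_spacing") %||% 1

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d px, spacing %.3g mm, HU range [%.1f, %.1f]\n",
              nrow(x), ncol(x), pixel_spacing(x), min(x), max(x)))
  invisible(x)
}

# strip class for arithmetic safety inside internals
hu_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "pixel_spacing") <- NULL
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map Hounsfield units to and from the normalized network domain
#'
#' The network operates on intensities affinely mapped from a display window
#' (default \[-1000, 2000\] HU) to \[0, 1\]. Values outside the window are
#' not clipped, so the mapping is exactly invertible.
#'
#' @param x numeric matrix or `ct_image`.
#' @param window length-2 HU window, default `c(-1000, 2000)`.
#' @return numeric matrix on the normalized (or HU) scale.
#' @export
normalize_hu <- function(x, window = c(-1000, 2000)) {
  (hu_matrix(x) - window[1]) / (window[2] - window[1])
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(x, window = c(-1000, 2000)) {
  hu_matrix(x) * (window[2] - window[1]) + window[1]
}
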