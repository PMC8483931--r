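#' Three-class tissue segmentation by k-means on HU values
#'
#' Clusters pixel HU values into air / water (including water-equivalent
#' soft tissue) / bone with k = 3, seeded deterministically by initializing
#' the centers at the 10th / 50th / 95th HU percentiles. The sorted cluster
#' centers are converted to two thresholds (midpoints between neighboring
#' centers); the water-bone threshold is raised to 320 HU whenever the
#' clustering yields a lower value, and labels are assigned by thresholding.
#'
#' @param image a [ct_image()] in HU.
#' @param seed integer seed guarding the k-means call.
#' @return a `tissue_segmentation`: list with `labels` (matrix of
#'   `"air"`/`"water"`/`"bone"`), `thresholds` (named: `air_water`,
#'   `water_bone`), `centers` (sorted cluster centers) and `water_mask`
#'   (0/1 matrix).
#' @examples
#' img <- generate_phantom(random_phantom_spec(64, seed = 3))
#' seg <- segment_tissues(img)
#' seg$thresholds
#' @export
segment_tissues <- function(image, seed = 1L) {
  label <- paste(deparse(substitute(image)), collapse = "")[1]
  image <- as_ct_image(image)
  hu <- hu_matrix(image)
  vals <- as.vector(hu)
  if (length(unique(vals)) < 3) {
    stop("degenerate clustering: image '", label,
         "' has fewer than 3 distinct HU values")
  }
  centers0 <- unname(quantile(vals, c(0.10, 0.50, 0.95)))
  lo <- centers0[1]; hi <- centers0[3]
  span <- hi - lo
  if (span == 0) {
    stop("degenerate clustering: image '", label,
         "' has an effectively constant HU histogram")
  }
  if (min(centers0[2] - lo, hi - centers0[2]) < 0.1 * span) {
    # the median falls inside an outer mode on skewed histograms (e.g. a
    # water region surrounded by mostly air), which would make k-means split
    # that mode and drag the air-water threshold into it. Re-seat the middle
    # center just inside the upper mode: splitting the high-HU mode is
    # harmless (the air-water midpoint stays between modes and the 320 HU
    # bone floor absorbs the upper split), splitting air is not.
    cand <- unique(unname(quantile(vals, seq(0, 1, by = 0.05))))
    lo <- min(cand); hi <- max(cand)
    inner <- cand[cand > lo & cand < hi]
    midspan <- (lo + hi) / 2
    upper <- inner[inner >= midspan]
    lower <- inner[inner < midspan]
    middle <- if (length(upper)) min(upper) else
      if (length(lower)) max(lower) else NA_real_
    centers0 <- c(lo, middle, hi)
    if (anyNA(centers0) || length(unique(centers0)) < 3) {
      stop("degenerate clustering: image '", label,
           "' does not separate into three HU clusters")
    }
  }
  # Lloyd iteration keeps the solution in the basin of the tissue-informed
  # initialization instead of jumping to a mode-splitting WSS optimum
  km <- withr::with_seed(
    as.integer(seed),
    suppressWarnings(kmeans(vals, centers = matrix(sort(centers0), ncol = 1),
                            algorithm = "Lloyd", iter.max = 100)))
  centers <- sort(as.vector(km$centers))
  thr_aw <- (centers[1] + centers[2]) / 2
  # a middle cluster at or above the bone floor means the image has no
  # water-equivalent tissue (e.g. air + bone only): everything above the
  # air-water threshold is then bone, and the water interval may be empty
  thr_wb <- if (centers[2] >= 320) 320 else
    max((centers[2] + centers[3]) / 2, 320)
  labels <- matrix("water", nrow(hu), ncol(hu))
  labels[hu < thr_aw] <- "air"
  labels[hu >= thr_wb] <- "bone"
  water_mask <- (labels == "water") + 0
  structure(list(labels = labels,
                 thresholds = c(air_water = thr_aw, water_bone = thr_wb),
                 centers = centers, water_mask = water_mask),
            class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<tissue_segmentation> air %.1f%% | water %.1f%% | bone %.1f%%; thresholds %.1f / %.1f HU\n",
    100 * sum(x$labels == "air") / n, 100 * sum(x$labels == "water") / n,
    100 * sum(x$labels == "bone") / n,
    x$thresholds[["air_water"]], x$thresholds[["water_bone"]]))
  invisible(x)
}

#' Clipped distance-transform weights over the water region
#'
#' For every water pixel, the exact Euclidean distance to the nearest
#' non-water pixel, clipped at the transition width `L`; non-water pixels
#' get 0. Interior water pixels (further than `L` from any boundary) thus
#' carry the full weight `L`, and a band of width `L` ramps linearly from
#' the boundary.
#'
#' @param segmentation a [segment_tissues()] result (or any list with a
#'   0/1 `water_mask` matrix).
#' @param L transition width in pixels (default 5, must be >= 1).
#' @return a `transition_weights`: list with `D` (weight matrix in
#'   \[0, L\]) and `L`.
#' @export
transition_weights <- function(segmentation, L = 5) {
  if (L < 1) stop("L must be >= 1")
  mask <- segmentation$water_mask
  stopifnot(is.matrix(mask))
  D <- if (!any(mask == 0)) {
    matrix(L, nrow(mask), ncol(mask))
  } else {
    dm <- EBImage::distmap(mask, metric = "euclidean")
    pmin(matrix(as.numeric(dm), nrow(mask), ncol(mask)), L)
  }
  structure(list(D = D, L = L), class = "transition_weights")
}

#' Distance-weighted mean over the water region
#'
#' `sum(D_i * y_i) / sum(D_i)`: interior water pixels (weight `L`) dominate,
#' boundary-band pixels contribute proportionally to their distance from the
#' region edge, and non-water pixels (weight 0) drop out.
#'
#' @param image_net a [ct_image()] (typically a network output).
#' @param weights a [transition_weights()] result.
#' @return scalar weighted mean in HU.
#' @export
weighted_water_mean <- function(image_net, weights) {
  img <- hu_matrix(as_ct_image(image_net))
  D <- weights$D
  if (!all(dim(img) == dim(D))) stop("weights and image shapes differ")
  sD <- sum(D)
  if (sD == 0) stop("no water pixels: all distance weights are zero")
  sum(D * img) / sD
}

#' Water-equivalent prior image
#'
#' Per-pixel convex blend between the image and the water mean:
#' `(D_i / L) * water_mean + (1 - D_i / L) * y_i`. Deep-interior water
#' pixels (`D = L`) become exactly the water mean, non-water pixels
#' (`D = 0`) are untouched, and the transition band interpolates linearly.
#'
#' @inheritParams weighted_water_mean
#' @param water_mean scalar, usually [weighted_water_mean()].
#' @return a [ct_image()].
#' @export
prior_image <- function(image_net, weights, water_mean) {
  image_net <- as_ct_image(image_net)
  img <- hu_matrix(image_net)
  D <- weights$D
  if (!all(dim(img) == dim(D))) stop("weights and image shapes differ")
  w <- D / weights$L
  ct_image(w * water_mean + (1 - w) * img,
           pixel_spacing = pixel_spacing(image_net))
}

#' Clustering-based water-equivalent tissue optimization
#'
#' The full post-processing chain applied to a denoised network output:
#' k-means tissue segmentation, clipped distance-transform transition
#' weights, distance-weighted water mean, and the prior-image blend. Images
#' without any water-class pixel are returned unchanged with a warning,
#' since the step is a refinement.
#'
#' @param image_net a [ct_image()] in HU (a network output).
#' @param L transition width in pixels (default 5).
#' @param seed integer seed for the segmentation.
#' @return list with `image` (optimized [ct_image()]), `segmentation`,
#'   `weights` and `water_mean` (`NA` when there is no water).
#' @examples
#' img <- generate_phantom(random_phantom_spec(64, seed = 3))
#' out <- optimize_tissues(img)
#' out$water_mean
#' @export
optimize_tissues <- function(image_net, L = 5, seed = 1L) {
  image_net <- as_ct_image(image_net)
  seg <- segment_tissues(image_net, seed = seed)
  if (!any(seg$water_mask == 1)) {
    warning("no water-class pixels; image returned unchanged")
    w <- structure(list(D = matrix(0, nrow(image_net), ncol(image_net)),
                        L = L), class = "transition_weights")
    return(list(image = image_net, segmentation = seg, weights = w,
                water_mean = NA_real_))
  }
  w <- transition_weights(seg, L = L)
  wm <- weighted_water_mean(image_net, w)
  list(image = prior_image(image_net, w, wm), segmentation = seg,
       weights = w, water_mean = wm)
}
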