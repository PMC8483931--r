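#' Elliptical phantom specifications
#'
#' A phantom is a square HU image painted from a list of ellipses on an air
#' background (-1000 HU), in the spirit of the Shepp-Logan construction.
#' Coordinates are relative: centers and semi-axes are fractions of the
#' canvas, so one spec renders at any resolution.
#'
#' @param canvas_size side length in pixels (>= 32).
#' @param ellipses list of ellipses built with [ellipse()].
#' @param hu_per_class named HU value per tissue class. Defaults follow CT
#'   convention (air -1000, water 0) with soft tissue 50 HU, bone 1000 HU
#'   (comfortably above the 320 HU bone floor used by the tissue
#'   segmentation) and metal 3000 HU.
#' @param seed integer seed recorded with the spec (phantom rendering itself
#'   is deterministic; the seed feeds downstream noise simulation).
#' @return a `phantom_spec` object.
#' @examples
#' spec <- phantom_spec(64, list(ellipse(0.5, 0.5, 0.3, 0.2, class = "water")))
#' img <- generate_phantom(spec)
#' @export
phantom_spec <- function(canvas_size,
                         ellipses = list(),
                         hu_per_class = c(air = -1000, soft = 50, water = 0,
                                          bone = 1000, metal = 3000),
                         seed = 1L) {
  if (canvas_size < 32) stop("canvas_size must be >= 32")
  stopifnot(is.list(ellipses))
  classes <- c("air", "soft", "water", "bone", "metal")
  if (!all(classes %in% names(hu_per_class))) {
    stop("hu_per_class must name all of: ", paste(classes, collapse = ", "))
  }
  if (hu_per_class[["air"]] != -1000 || hu_per_class[["water"]] != 0) {
    stop("by convention air must map to -1000 HU and water to 0 HU")
  }
  if (hu_per_class[["bone"]] < 320) {
    stop("bone HU must be >= 320 (clustering bone-water floor)")
  }
  for (e in ellipses) validate_ellipse(e)
  structure(list(canvas_size = as.integer(canvas_size), ellipses = ellipses,
                 hu_per_class = hu_per_class, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param cx,cy ellipse center, relative coordinates in (0, 1).
#' @param a,b semi-axes as fractions of the canvas.
#' @param angle rotation in degrees (counter-clockwise).
#' @param class tissue class, one of air/soft/water/bone/metal.
#' @export
ellipse <- function(cx, cy, a, b, angle = 0, class = "water") {
  e <- list(cx = cx, cy = cy, a = a, b = b, angle = angle, class = class)
  validate_ellipse(e)
  e
}

validate_ellipse <- function(e) {
  stopifnot(all(c("cx", "cy", "a", "b", "angle", "class") %in% names(e)))
  if (!e$class %in% c("air", "soft", "water", "bone", "metal")) {
    stop("unknown tissue class: ", e$class)
  }
  if (e$a <= 0 || e$b <= 0) stop("semi-axes must be positive")
  th <- e$angle * pi / 180
  ex <- sqrt((e$a * cos(th))^2 + (e$b * sin(th))^2)
  ey <- sqrt((e$a * sin(th))^2 + (e$b * cos(th))^2)
  if (e$cx - ex < 0 || e$cx + ex > 1 || e$cy - ey < 0 || e$cy + ey > 1) {
    stop("ellipse extends outside the unit canvas")
  }
  invisible(e)
}

#' Render a phantom specification to a CT image
#'
#' Pixels covered by several ellipses take the HU of the last-listed one;
#' uncovered pixels are air (-1000 HU). Rendering is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return a [ct_image()] of size `canvas_size` x `canvas_size`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$canvas_size
  # pixel centers in relative coordinates; rows index y, columns x
  xs <- (seq_len(n) - 0.5) / n
  px <- matrix(xs, n, n, byrow = TRUE)   # x varies along columns
  py <- matrix(xs, n, n)                 # y varies along rows
  img <- matrix(spec$hu_per_class[["air"]], n, n)
  for (e in spec$ellipses) {
    th <- e$angle * pi / 180
    dx <- px - e$cx
    dy <- py - e$cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / e$a)^2 + (v / e$b)^2 <= 1
    img[inside] <- spec$hu_per_class[[e$class]]
  }
  ct_image(img)
}

#' Draw a random multi-ellipse phantom specification
#'
#' Convenience generator for training/evaluation variety: a soft-tissue body
#' ellipse containing a few water-equivalent regions and optionally a bone
#' insert. Fully determined by `seed`.
#'
#' @param canvas_size side length in pixels.
#' @param n_water number of interior water-equivalent ellipses.
#' @param with_bone include a small bone insert?
#' @param seed integer seed.
#' @return a `phantom_spec`.
#' @export
random_phantom_spec <- function(canvas_size = 128, n_water = 3,
                                with_bone = TRUE, seed = 1L) {
  withr::with_seed(seed, {
    es <- list(ellipse(0.5, 0.5, runif(1, 0.32, 0.4), runif(1, 0.28, 0.38),
                       angle = runif(1, 0, 180), class = "soft"))
    for (i in seq_len(n_water)) {
      es[[length(es) + 1L]] <- ellipse(runif(1, 0.38, 0.62),
                                       runif(1, 0.38, 0.62),
                                       runif(1, 0.05, 0.14),
                                       runif(1, 0.05, 0.14),
                                       angle = runif(1, 0, 180),
                                       class = "water")
    }
    if (with_bone) {
      es[[length(es) + 1L]] <- ellipse(runif(1, 0.42, 0.58),
                                       runif(1, 0.30, 0.38),
                                       0.04, 0.03, angle = runif(1, 0, 180),
                                       class = "bone")
    }
    phantom_spec(canvas_size, es, seed = seed)
  })
}
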