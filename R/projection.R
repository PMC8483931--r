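#' Parallel-beam sinogram container
#'
#' Projection-domain data: one row per view angle, one column per detector
#' bin, holding line integrals of linear attenuation (unitless). Angles are
#' evenly spaced over \[0, 180) degrees; `det_spacing` is in mm.
#'
#' @param values numeric matrix (n_angles x n_detectors).
#' @param angles view angles in degrees.
#' @param det_spacing detector pitch in mm.
#' @param mu_water linear attenuation of water (1/mm) used for HU conversion.
#' @param incident_photons photon count I0 used when noise was injected, or
#'   `NULL` for a clean sinogram.
#' @return a `sinogram` object.
#' @export
sinogram <- function(values, angles, det_spacing = 1, mu_water = 0.02,
                     incident_photons = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(angles)) stop("one angle per sinogram row")
  if (nrow(values) < 16) stop("need at least 16 view angles")
  if (!is.null(incident_photons) && incident_photons <= 0) {
    stop("incident_photons must be positive")
  }
  structure(values, angles = angles, det_spacing = det_spacing,
            mu_water = mu_water, incident_photons = incident_photons,
            class = c("sinogram", "matrix", "array"))
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d detectors, I0 = %s\n",
              nrow(x), ncol(x),
              if (is.null(attr(x, "incident_photons"))) "none (clean)" else
                format(attr(x, "incident_photons"))))
  invisible(x)
}

# vectorized bilinear interpolation, zero outside the grid
bilinear_at <- function(m, r, c) {
  n1 <- nrow(m); n2 <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n1 & ci >= 1 & ci <= n2
    out <- numeric(length(ri))
    if (any(ok)) out[ok] <- m[cbind(ri[ok], ci[ok])]
    out
  }
  gather(r0, c0) * (1 - fr) * (1 - fc) +
    gather(r0 + 1, c0) * fr * (1 - fc) +
    gather(r0, c0 + 1) * (1 - fr) * fc +
    gather(r0 + 1, c0 + 1) * fr * fc
}

hu_to_mu <- function(hu, mu_water) pmax(mu_water * (1 + hu / 1000), 0)

#' Forward projection (radon transform) of a CT image
#'
#' Converts HU to linear attenuation (mu = mu_water * (1 + HU/1000), clipped
#' at 0) and integrates along parallel rays for evenly spaced angles over
#' \[0, 180) degrees, by ray sampling with bilinear interpolation.
#'
#' @param image a [ct_image()] (finite HU values).
#' @param n_angles number of view angles (>= 16), default 180.
#' @param mu_water water attenuation coefficient in 1/mm (default 0.02).
#' @param n_detectors number of detector bins; default the smallest odd
#'   count covering the image diagonal.
#' @param step ray sampling step in pixels (default 0.5).
#' @return a [sinogram()].
#' @export
forward_project <- function(image, n_angles = 180, mu_water = 0.02,
                            n_detectors = NULL, step = 0.5) {
  image <- as_ct_image(image)
  if (n_angles < 16) stop("need at least 16 view angles")
  n <- nrow(image); m <- ncol(image)
  if (n != m) stop("forward_project expects a square image")
  spacing <- pixel_spacing(image)
  mu <- hu_to_mu(hu_matrix(image), mu_water)

  if (is.null(n_detectors)) {
    n_detectors <- ceiling(sqrt(2) * n) + 3
    if (n_detectors %% 2 == 0) n_detectors <- n_detectors + 1
  }
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  tpos <- (seq_len(n_detectors) - (n_detectors + 1) / 2)  # px
  smax <- (n_detectors - 1) / 2
  svals <- seq(-smax, smax, by = step)
  ctr <- (n + 1) / 2

  sino <- matrix(0, n_angles, n_detectors)
  tt <- rep(tpos, times = length(svals))
  ss <- rep(svals, each = length(tpos))
  for (ia in seq_len(n_angles)) {
    th <- angles[ia] * pi / 180
    x <- tt * cos(th) - ss * sin(th)
    y <- tt * sin(th) + ss * cos(th)
    vals <- bilinear_at(mu, y + ctr, x + ctr)
    sino[ia, ] <- rowSums(matrix(vals, n_detectors, length(svals))) *
      step * spacing
  }
  sinogram(sino, angles, det_spacing = spacing, mu_water = mu_water)
}

# discrete Ram-Lak (band-limited ramp) filter kernel, real space
ramlak_kernel <- function(n_detectors, tau) {
  idx <- -(n_detectors - 1):(n_detectors - 1)
  h <- numeric(length(idx))
  h[idx == 0] <- 1 / (4 * tau^2)
  odd <- idx %% 2 != 0
  h[odd] <- -1 / (pi^2 * idx[odd]^2 * tau^2)
  h
}

#' Filtered back projection reconstruction
#'
#' Ramp-filters each projection (discrete Ram-Lak kernel applied by FFT
#' convolution) and backprojects with linear detector interpolation, then
#' converts the attenuation map back to HU.
#'
#' @param sino a [sinogram()].
#' @param size output image side length in pixels.
#' @return a [ct_image()].
#' @export
fbp_reconstruct <- function(sino, size) {
  stopifnot(inherits(sino, "sinogram"))
  angles <- attr(sino, "angles")
  tau <- attr(sino, "det_spacing")
  mu_water <- attr(sino, "mu_water")
  p <- unclass(sino)
  nd <- ncol(p)
  na <- nrow(p)

  h <- ramlak_kernel(nd, tau)
  L <- 2^ceiling(log2(3 * nd))
  hf <- fft(c(h, numeric(L - length(h))))
  q <- matrix(0, na, nd)
  for (ia in seq_len(na)) {
    pf <- fft(c(p[ia, ], numeric(L - nd)))
    conv <- Re(fft(pf * hf, inverse = TRUE)) / L
    q[ia, ] <- conv[nd:(2 * nd - 1)] * tau
  }

  ctr <- (size + 1) / 2
  xs <- (seq_len(size) - ctr) * tau
  px <- matrix(xs, size, size, byrow = TRUE)
  py <- matrix(xs, size, size)
  t1 <- -(nd - 1) / 2 * tau
  recon <- matrix(0, size, size)
  for (ia in seq_len(na)) {
    th <- angles[ia] * pi / 180
    t <- px * cos(th) + py * sin(th)
    fi <- (t - t1) / tau + 1
    i0 <- floor(fi)
    fr <- fi - i0
    ok0 <- i0 >= 1 & i0 <= nd
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nd
    v <- numeric(length(fi))
    v[ok0] <- q[ia, i0[ok0]] * (1 - fr[ok0])
    v[ok1] <- v[ok1] + q[ia, i0[ok1] + 1] * fr[ok1]
    recon <- recon + v
  }
  mu <- recon * pi / na
  ct_image(1000 * (mu / mu_water - 1), pixel_spacing = tau)
}

#' Inject photon (Poisson) noise into a sinogram
#'
#' Line integrals are converted to transmission counts `I0 * exp(-p)`,
#' Poisson counts are drawn (Gaussian large-count limit above 1e7 expected
#' counts), an optional additive Gaussian electronic-noise term can be
#' enabled, counts are floored at 1, and the noisy line integrals are
#' recovered by the log transform.
#'
#' @param sino a clean [sinogram()].
#' @param incident_photons photons per detector bin at zero attenuation (> 0).
#' @param seed integer seed; the draw is fully reproducible.
#' @param gaussian_sd standard deviation of optional additive Gaussian noise
#'   on the counts (default 0, disabled).
#' @return a [sinogram()] with `incident_photons` recorded.
#' @export
add_projection_noise <- function(sino, incident_photons, seed,
                                 gaussian_sd = 0) {
  stopifnot(inherits(sino, "sinogram"))
  if (incident_photons <= 0) stop("incident_photons must be positive")
  p <- unclass(sino)
  lambda <- incident_photons * exp(-p)
  counts <- withr::with_seed(as.integer(seed), {
    out <- numeric(length(lambda))
    big <- lambda > 1e7
    if (any(!big)) out[!big] <- rpois(sum(!big), lambda[!big])
    if (any(big)) {
      out[big] <- lambda[big] + sqrt(lambda[big]) * rnorm(sum(big))
    }
    if (gaussian_sd > 0) out <- out + rnorm(length(out), sd = gaussian_sd)
    out
  })
  counts <- pmax(counts, 1)
  noisy <- log(incident_photons) - log(counts)
  sinogram(matrix(noisy, nrow(p), ncol(p)), attr(sino, "angles"),
           det_spacing = attr(sino, "det_spacing"),
           mu_water = attr(sino, "mu_water"),
           incident_photons = incident_photons)
}

#' Simulate a low-dose CT image from a normal-dose image
#'
#' The full projection-domain pipeline: forward projection, Poisson noise on
#' transmission counts at the requested dose, and filtered back projection
#' to an image of the same size. Deterministic given `seed`.
#'
#' @inheritParams forward_project
#' @inheritParams add_projection_noise
#' @return a [ct_image()] with the same dimensions as `image`.
#' @examples
#' nd <- generate_phantom(random_phantom_spec(64, seed = 7))
#' ld <- simulate_low_dose(nd, incident_photons = 1e4, seed = 7)
#' @export
simulate_low_dose <- function(image, incident_photons, seed, n_angles = 180,
                              mu_water = 0.02, gaussian_sd = 0) {
  image <- as_ct_image(image)
  if (incident_photons <= 0) stop("incident_photons must be positive")
  sino <- forward_project(image, n_angles = n_angles, mu_water = mu_water)
  noisy <- add_projection_noise(sino, incident_photons, seed,
                                gaussian_sd = gaussian_sd)
  fbp_reconstruct(noisy, size = nrow(image))
}
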