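# Shared fixtures: small deterministic images, phantoms and models used
# across the suite. Everything is generated in code at test time.

# smooth synthetic image (Gaussian soft-tissue bumps on air), good for
# round-trip reconstruction checks because it has no step edges
smooth_phantom_image <- function(n = 64) {
  xs <- (seq_len(n) - 0.5) / n
  gx <- matrix(xs, n, n, byrow = TRUE)
  gy <- matrix(xs, n, n)
  hu <- -1000 +
    1050 * exp(-((gx - 0.5)^2 + (gy - 0.5)^2) / (2 * 0.15^2)) +
    200 * exp(-((gx - 0.6)^2 + (gy - 0.4)^2) / (2 * 0.08^2))
  ct_image(hu)
}

# uniform water disc on air, optionally with additive Gaussian noise
water_disc_image <- function(n = 64, radius = 0.3, noise_sd = 0, seed = 1) {
  base <- generate_phantom(
    phantom_spec(n, list(ellipse(0.5, 0.5, radius, radius, class = "water"))))
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, matrix(rnorm(n * n, 0, noise_sd), n, n))
    base <- ct_image(unclass(base) + noise)
  }
  base
}

# tiny model for fast training tests
tiny_model <- function(seed = 1, S = 1, n_layers = 4, kernels = 8) {
  build_model(red_config(n_layers = n_layers,
                         kernels_per_hidden_layer = kernels),
              seed = seed, S = S)
}

zero_weights <- function(model) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W[] <- 0
    model$layers[[l]]$b[] <- 0
  }
  model
}

# independent brute-force ray-summation radon oracle: fixed-step sampling
# along the ray with nearest-pixel lookup on a fine subgrid
ray_sum_oracle <- function(image, angle_deg, t_px, step = 0.05) {
  m <- unclass(image)
  mu <- pmax(0.02 * (1 + m / 1000), 0)
  n <- nrow(m)
  th <- angle_deg * pi / 180
  smax <- n  # generous ray extent
  svals <- seq(-smax, smax, by = step)
  x <- t_px * cos(th) - svals * sin(th)
  y <- t_px * sin(th) + svals * cos(th)
  ctr <- (n + 1) / 2
  ri <- round(y + ctr); ci <- round(x + ctr)
  ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
  sum(mu[cbind(ri[ok], ci[ok])]) * step
}

# parameters of a model serialized to a canonical byte payload
parameter_payload <- function(model) {
  serialize(lapply(model$layers, function(l) list(W = l$W, b = l$b)),
            connection = NULL)
}
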