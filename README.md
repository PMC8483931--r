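# redct

Low-dose CT image denoising with a weight-shared recursive residual
encoder-decoder network, a joint pixel + perceptual training loss, and a
clustering-based water-equivalent tissue optimization — plus a
projection-domain noise simulator so the whole method can be trained and
verified on synthetic phantom data. It is aimed at researchers working on
CT image restoration who want a self-contained, reproducible reference
implementation of this family of methods in R.

## The method

Lowering X-ray dose lowers the photon count per detector bin; the filtered
back projection (FBP) reconstruction of the noisy projections shows grainy
noise and streak artifacts. `redct` learns the mapping G : z → x from a
low-dose image z to its normal-dose counterpart x in three parts:

**1. Recursive shallow RED network.** A shallow residual encoder-decoder
(RED) network F is applied S times with one shared parameter set:

    I_1 = concat(X, X)
    O_s = I_s[,,1] − F(I_s)          (global residual: F predicts detail)
    I_{s+1} = concat(O_s, X)         for 1 ≤ s < S

where X is the noisy input. The shallow network has 8 layers — 4 valid
(unpadded, stride-1) 3×3 convolutions and 4 mirrored transposed
convolutions, 64 kernels per hidden layer, 1 in the last — with symmetric
encoder→decoder skip additions and ReLU activations, weights initialized
from N(0, 0.01²). Weight sharing makes the parameter count independent of
S while the effective depth grows; the multiply-count complexity is
S · Σ_l n_(l−1) f_l² n_l.

**2. Joint loss.** L_Joint = L_MSE + L_Per, the per-pixel squared error
plus a perceptual term ‖φ(O_S) − φ(y)‖² / (W_i H_i) computed on feature
maps of a frozen convolutional extractor (seeded random features by
default; a loader hook accepts pretrained weights).

**3. Water-equivalent tissue optimization.** The denoised image is
segmented into air / water / bone by seeded k-means on HU (water-bone
threshold floored at 320 HU); D is the Euclidean distance transform of the
water mask clipped at L = 5 px; the water region is blended toward its
D-weighted mean:

    ȳ_w = Σ D_i y_i / Σ D_i
    y_i^prior = (D_i/L) ȳ_w + (1 − D_i/L) y_i

so deep-interior water becomes exactly uniform, boundaries transition
linearly, and non-water pixels are untouched.

The simulator adds noise where it physically arises — in the projection
domain: forward projection of μ = μ_water(1 + HU/1000), Poisson noise on
transmission counts I0·exp(−p), log transform, and ramp-filtered FBP.

## Worked example

Simulate a paired phantom, train a small model, and score a held-out pair:

```r
library(redct)

ndct <- generate_phantom(random_phantom_spec(128, seed = 7))
ldct <- simulate_low_dose(ndct, incident_photons = 1e4, seed = 7)

patches <- extract_patches(ldct, ndct, patch_size = 16, n_patches = 400, seed = 7)
cfg <- train_config(learning_rate = 1e-3, max_iterations = 300,
                    checkpoint_every = 300, batch_size = 4,
                    patch_size = 16, seed = 7)
model <- build_model(red_config(), seed = 7, S = 2)
fit <- train_model(model, patches, cfg)
fit
#> <train_result> 300 iterations, final joint loss 0.00093298

ndct2 <- generate_phantom(random_phantom_spec(128, seed = 1007))
ldct2 <- simulate_low_dose(ndct2, incident_photons = 1e4, seed = 1007)
pairs <- tibble::tibble(image_id = "held_out",
                        ndct = list(ndct2), ldct = list(ldct2))
evaluate_pipeline(fit$model, pairs, with_optimization = TRUE, seed = 7)
#> <redct_report> 3 records, 3 methods
#>        method n mean_psnr mean_ssim display_psnr display_ssim
#>      denoised 1  38.57227 0.9976159       38.572        0.998
#>  denoised_opt 1  40.11311 0.9983169       40.113        0.998
#>          ldct 1  34.33268 0.9934486       34.333        0.993
```

On this held-out pair the network lifts PSNR from 34.3 dB (raw low-dose)
to 38.6 dB, and the tissue optimization adds another 1.5 dB by flattening
residual noise in the water-equivalent regions. `tidy()` returns the
per-image rows, `glance()` the per-method averages, and `autoplot()` works
on images, reports and training logs.

The training defaults in `train_config()` document the full-scale protocol
(learning rate 1e-5, 48 px patches, 50,000 iterations, S = 5); the example
above uses the desk-scale profile described in the methods vignette
(`vignettes/redct-methods.Rmd`).

A command-line tool wrapping these functions ships in `inst/cli/redct`
(subcommands `simulate`, `train`, `denoise`, `optimize`, `evaluate`).

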