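# semsr — GAN resolution enhancement for scanning electron microscopy

`semsr` is an R toolkit for deep-learning super-resolution of SEM
micrographs. SEM resolution at fixed field of view is set by the pixel
sampling: halving the pixel pitch quadruples the scanned pixels and, at equal
dwell time, the electron dose — which charges and damages beam-sensitive
specimens. `semsr` instead acquires (or simulates) a coarse scan and restores
the fine-pitch image with a conditional GAN trained on co-registered
coarse/fine pairs of the same fields of view, giving the resolution of the
fine scan at a quarter of the dose.

The package is aimed at microscopists and image-analysis developers who want
a reproducible, fully-seeded reference implementation of the complete
pipeline: specimen simulation, acquisition degradation modelling,
co-registration, patch preparation, GAN training, tiled inference, and
resolution quantification.

## The model

The generator `G` (a U-Net: two-convolution blocks with leaky ReLUs, 2x
pooling, skip connections, resize-convolution upsampling) maps the
Lanczos-upsampled, mean/std-normalized low-resolution image `x` to the
normalized high-resolution target `z`. It minimizes

```
l_generator = L1{G(x), z} + alpha * TV{G(x)} + beta * [1 - D(G(x))]^2
L1{G(x), z} = (1 / (M N)) * sum_ij |z_ij - G(x)_ij|
TV{G(x)}    = sum_ij (|G(x)_{i+1,j} - G(x)_{i,j}| + |G(x)_{i,j+1} - G(x)_{i,j}|)
```

against a VGG-style discriminator `D` (sigmoid score in [0, 1]) trained on

```
l_discriminator = D(G(x))^2 + (1 - D(z))^2
```

updated every fourth generator iteration. `calibrate_loss_weights()` picks
`alpha`, `beta` so the adversarial, L1 and TV terms form 84% / 14% / 2% of
the generator total (unit raw terms give `alpha = 1/7`, `beta = 6`).

Resolution gain is quantified two ways:

- **Gap resolvability** — along a profile through two adjacent
  nanoparticles, a gap exists if the valley falls below 60% of the flanking
  peak intensity; its width is the distance between the 80%-of-peak
  crossings (sub-sample, by linear interpolation).
- **Radially-averaged power spectra** — recovered magnitude above the input
  Nyquist frequency (1/(2 x 14.2 nm) ≈ 0.035 cycles/nm).

Since no deep-learning framework ships in the supported environment, the
networks, backprop and Adam are implemented in the package itself
(im2col/GEMM convolutions via RcppArmadillo), validated against finite
differences.

## Worked example

Simulate a gold-on-carbon-like specimen, degrade it to the coarse
acquisition, train the desk-scale network, and measure gap statistics:

```r
library(semsr)

field <- generate_particle_field(16, fov_nm = 1420, near_pair_fraction = 0.75,
                                 gap_range_nm = c(5, 40),
                                 pair_radius_range_nm = c(20, 45), seed = 102)
high <- render_highres(field, pixel_size_nm = 7.1)      # 200 x 200 px
low  <- degrade(high, degradation_config(psf_sigma_nm = 8,
                                         downsample_factor = 2, seed = 1102))
print(low)
#> <sem_image> 100 x 100 px @ 14.2 nm/px  [0, 1.08]

# the gap rule on a minimal three-sample profile: peaks 1.0, valley 0.5,
# sample spacing 7.1 nm -> 80%-of-peak crossings 8.52 nm apart
measure_gap(structure(list(positions_nm = c(0, 7.1, 14.2),
                           intensities = c(1, 0.5, 1)),
                      class = "line_profile"))$width_nm
#> [1] 8.52

calibrate_loss_weights(1, 1, 1)[c("alpha", "beta")]
#> $alpha
#> [1] 0.1428571
#> $beta
#> [1] 6

electron_dose_ratio(7.1, 14.2)
#> [1] 4
```

The full demo pipeline (simulate -> register -> prepare -> train -> enhance
-> evaluate) runs from a YAML config:

```r
cfg <- pipeline_config(overrides = list(seed = 5, out_dir = "semsr_run"))
run_all(cfg)   # writes images, reports and evaluation.json under semsr_run/
```

or from the command line:

```sh
Rscript -e 'semsr::semsr_main()' run-all \
  --config "$(Rscript -e 'cat(system.file("extdata/demo-config.yaml", package="semsr"))')" \
  --seed 5
```

In the end-to-end acceptance study (50 training + 10 held-out simulated
pairs, 360 planted gaps, 2,000 desk-scale iterations) the network output
resolves more gaps than the Lanczos-upsampled input and cuts the mean
absolute gap-width error by well over 25% (about 11 nm to 2–4 nm on held-out
images), while recovering spectral magnitude above the input Nyquist in all
annular bins — the desk-scale analogue of the directional claims the method
makes at full scale.

## Layout

- `R/synth_specimen.R` — particle fields, rendering, aliasing degradation,
  beam-damage warp
- `R/registration.R` — Lanczos upsampling, correlation affine, pyramid
  elastic registration
- `R/patch_prep.R` — normalization, tiling, correlation filtering, dihedral
  augmentation
- `R/nn.R`, `R/gan_sr.R`, `src/conv_ops.cpp` — networks, losses, training,
  tiled inference
- `R/evaluation.R` — gap resolvability, Gaussian fits, radial spectra
- `R/pipeline.R` — YAML-configured, resumable stage runner and CLI
- `vignettes/semsr-methods.Rmd` — modelling assumptions, parameter
  rationale, limitations
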