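# vistar

Quantitative analysis for **label-free vibrational imaging of
hydrogel-expanded tissues**: stimulated Raman scattering (SRS) at the
protein CH3 stretch (2940 cm⁻¹) images endogenous protein density; physically
swelling the specimen in a hydrogel magnifies it ~4× before the optics, so a
conventional SRS microscope resolves structure well below its diffraction
limit without any fluorophore. `vistar` implements the computational side of
that workflow for microscopists and image analysts:

* **Resolution calibration** from sub-resolution bead images. The bead image
  is a uniform circle of diameter *d* convolved with the (Gaussian) lateral
  PSF. From a fitted cross-section FWHM *m*, the PSF FWHM *g* solves
  `FWHM(disk(d) ⊗ Gaussian(g)) = m` by monotone root search on the analytic
  forward profile; the resolution figure is `1.22 · g` (Rayleigh criterion),
  and the **effective** resolution after linear expansion *E* is that value
  divided by *E*.
* **Expansion-ratio estimation** by registering pre/post-expansion
  projections: phase correlation of log-polar-resampled Fourier magnitudes
  recovers scale and rotation (Fourier–Mellin), refined by image correlation.
* **Protein-retention quantification**: linear expansion by *E* dilutes
  conserved per-voxel signal by *E*³, so
  `retention = mean_expanded · E³ / mean_original` on matched cell masks and
  `loss% = 100·(1 − retention)`.
* **Virtual staining**: a from-scratch U-Net (Rcpp/RcppArmadillo: im2col GEMM
  convolutions, max pooling, bilinear upsampling, Adam on MSE) trained on
  paired CH3/fluorescence slices predicts fluorescence-equivalent channels
  (v-DAPI nuclei, v-lectin vessels, v-MAP2 somata+dendrites, v-NeuN neurons)
  from the single label-free CH3 channel, with rolling-ball background
  subtraction and percentile normalization, tiled overlapping inference, and
  masked Pearson-r evaluation.
* **A seeded phantom generator** (beads, multi-structure tissue fields,
  pre/post-expansion pairs with ground truth) so the full pipeline is
  testable without microscope data.

All lengths are nanometers; volumes are `(z, y, x)` arrays with pixel-size
metadata, read/written as multi-page grayscale TIFF (float32 on write) plus a
JSON sidecar.

## Worked example

```r
library(vistar)

# A 100 nm bead imaged with a fitted cross-section FWHM of 320 nm:
dec <- deconvolve_bead(measured_fwhm = 320, bead_diameter = 100)
dec$psf_fwhm              # 314.4  (nm, Gaussian PSF after removing the bead size)
dec$rayleigh_resolution   # 383.6  (nm, 1.22 x PSF FWHM)
effective_resolution(dec$rayleigh_resolution, 4.2)   # 91.3 -> reports as 91 nm

# The same figure through the full pipeline on a synthetic bead field:
bs  <- generate_bead_stack(diameter = 100, psf_fwhm = dec$psf_fwhm,
                           pixel_size = 20, n_beads = 12, seed = 1)
calibrate_from_stack(bs$volume, bead_diameter = 100, expansion_factor = 4.2)
#> <resolution_report>
#>   beads fitted          : 24 profiles on 12 beads
#>   measured FWHM         : 320.6 nm (bead diameter 100 nm)
#>   deconvolved PSF FWHM  : 315.1 nm
#>   Rayleigh resolution   : 384.4 nm
#>   effective resolution  : 92 nm at 4.2x expansion

# Expansion ratio and retention on a phantom expanded 4x:
ph  <- generate_tissue_phantom(phantom_spec(seed = 1))
ex  <- simulate_expansion(ph, ratio = 4)
est <- estimate_expansion_ratio(ex$pre[["CH3-2940"]], ex$post[["CH3-2940"]])
#> <expansion_estimate> ratio 4.002 (scale 1.000, rot 0.00 deg, peak z 102.2, residual 13 nm)
measure_retention(ex$post[["CH3-2940"]], ex$pre[["CH3-2940"]],
                  truth_mask(ex$truth, "nucleus", 12),
                  truth_mask(ph$truth, "nucleus", 4), est$ratio)
#> <retention_report> retention 1.007 (loss -0.7%) at 4.00187x expansion (dilution 64.0897)
```

The measured 320.6 nm is the Gaussian-fit width of the rendered bead
profiles; deconvolving the 100 nm object and applying the Rayleigh factor
gives the microscope resolution (~384 nm), which a 4.2× expansion converts
to ~91 nm in pre-expansion sample coordinates. On the phantom, registration
recovers the simulated 4× swelling to 0.05 %, and the retention report —
after undoing the 4³ = 64-fold signal dilution — confirms that all protein
was conserved (retention ≈ 1).

Training and evaluating a virtual-staining channel:

```r
phs <- lapply(1:8, function(i)
  generate_tissue_phantom(phantom_spec(field_shape = c(1, 128, 128), seed = 300 + i)))
cfg <- train_config(patch_size = 48, batch_size = 8, steps = 400,
                    depth = 2, base_channels = 8, rolling_ball_radius = 15)
ds  <- build_dataset(lapply(phs, `[[`, c("channels", "CH3-2940")),
                     lapply(phs, `[[`, c("channels", "lectin")), cfg)
m   <- train_unet(ds, cfg)
evaluate_predictions(m, ds, mask_rule = "signal_images_only")
#> <evaluation_report> pooled r = 0.9061 over 2 image(s) [signal_images_only]
```

A `vista` command-line wrapper (installed under `exec/`) exposes the same
operations: `simulate`, `calibrate-resolution`, `expansion-ratio`,
`retention`, `train`, `predict`, `evaluate`, `noise-curve`, `merge`.

## Package layout

* `R/volume.R` — image-volume container, TIFF/JSON I/O, projections, merges
* `R/phantom.R` — phantom specs, renderers, SRS forward model, expansion
* `R/resolution.R` — profile fitting, deconvolution, resolution reports
* `R/expansion.R` — log-polar registration, retention, segmentation
* `R/prediction.R`, `src/unet.cpp` — U-Net training and tiled inference
* `R/evaluation.R` — Pearson metrics, masking, noise-robustness curve
* `R/cli.R`, `exec/vista` — command-line surface
* `vignettes/vista-methods.Rmd` — models, assumptions, parameter choices
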