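---
title: "Models and methods behind vistar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vistar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vistar)
```

`vistar` analyses label-free vibrational (SRS) images of hydrogel-expanded,
protein-retained samples. This vignette records the models the package
implements, the assumptions behind them, the parameters that matter, and the
choices we made where the design was genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinate and unit conventions

Volumes are `(z, y, x)` arrays; all physical lengths are nanometers (mixing
nm and µm across modules is a classic source of silent errors). In-plane
physical length of a segment is pixel count × `pixel_size_xy`, and for
expanded samples that is a *post-expansion* length; dividing by the linear
expansion factor converts back to pre-expansion sample coordinates.
Sixteen-bit acquisitions are promoted to float **without rescaling**, because
retention quantification compares absolute mean intensities between images.
No detector-offset subtraction is applied at I/O time; background handling
is explicit (rolling ball) where a module needs it.

Volumes are written as uncompressed float32 multi-page TIFF. The writer is
implemented in the package because the CRAN `tiff` package writes 32-bit
pages as scaled integers, which cannot round-trip float voxel data
bit-exactly; reading still goes through `tiff::readTIFF`, which handles
8/16-bit integer and float pages. Metadata travel in a JSON sidecar rather
than TIFF tags: bit-exact, dialect-free, and diff-able.

## Resolution calibration

A sub-resolution polystyrene bead images as its object function convolved
with the lateral PSF. Following the field's usual simulation treatment, the
bead is modeled as a **uniform circle** of diameter $d$ (not a projected
sphere) and the PSF as an isotropic 2-D Gaussian of FWHM $g$. The central
line profile of the convolution reduces to a 1-D integral over chords,

$$I(x) = \int_{-R}^{R} \frac{1}{\sigma}\varphi\!\left(\frac{x-u}{\sigma}\right)
\left(2\Phi\!\left(\frac{\sqrt{R^2-u^2}}{\sigma}\right)-1\right)\,du ,$$

with $R = d/2$, $\sigma = g/2\sqrt{2\ln 2}$, evaluated by Simpson quadrature
on a grid far finer (hundreds of nodes across the disc) than the FWHM being
measured. `deconvolve_bead()` inverts the map $g \mapsto
\mathrm{FWHM}(I)$ by `uniroot`; the map is strictly increasing, so the root
is unique whenever the measured FWHM exceeds the bare object width. Widths
are *not* subtracted in quadrature — disk ⊗ Gaussian FWHMs do not subtract
that way, which is the reason for the forward-model root search.

Two numerically equal definitions of "measured FWHM" coexist: the half-max
crossing of the true profile, and $2\sqrt{2\ln2}\,\hat\sigma$ from a
least-squares Gaussian fit. For $d/g \lesssim 0.5$ they agree to well under
1 nm (the profile is very nearly Gaussian), so fitting bead cross-sections
with `fit_gaussian()` and inverting with the half-max forward model is
self-consistent. The fit supplies an analytic gradient; numeric
differentiation fails when a start value (a centered peak, a zero offset)
is exactly zero.

**Rayleigh conversion.** The resolution figure is $1.22 \times g$. With the
320 nm / 100 nm worked example this lands within half a percent of the
382 nm headline figure the pipeline reproduces. An alternative reading — applying an
Airy-equivalent factor ($0.61/0.51 \approx 1.194$) directly to the measured
320 nm without object deconvolution — produces nearly the same number, and
the exact constant used upstream is not recoverable; we standardize on
"deconvolve, then 1.22", and expose `rayleigh_factor` for users who prefer
the other convention.

**Effective resolution** after linear expansion $E \ge 1$ is the optical
resolution divided by $E$: the gel magnifies the sample before the optics.
The function returns the unrounded value; reports round to whole
nanometers.

`calibrate_from_stack()` detects beads as local maxima of the lightly
smoothed projection above a robust `median + 5·MAD` threshold (the source
material does not describe detection; this is our choice), merges
duplicates within one estimated FWHM, fits two orthogonal profiles per
bead, and averages. Axial resolution is not estimated.

## Expansion ratio by registration

`estimate_expansion_ratio()` works on 2-D maximum-intensity projections —
pre- and post-expansion stacks sample physically different z-planes, so 3-D
registration of desk-scale stacks is ill-posed. The scale/rotation estimate
is Fourier–Mellin: Hann window, FFT magnitude with the Reddy–Chatterji
high-pass, log-polar resampling (540 angles × 512 log-radii), and phase
correlation with parabolic sub-pixel peak interpolation.

Numerical choices that proved load-bearing:

* Both projections are first brought to comparable sizes by power-of-two
  block averaging (undone in the final ratio). This keeps the two spectra
  on overlapping log-radius ranges and makes the residual scale ≈ 1.
* The log-polar magnitudes are log-compressed and the per-radius mean is
  removed. Image spectra share a generic radial decay; without this
  normalization the correlation locks onto zero scale shift for noisy
  inputs.
* The peak search is restricted to the physically admissible band
  (rotation within ±35°, residual scale within 2.5×); rotations beyond
  ±30° raise a registration-failure error rather than returning a wrong
  mode.
* The scale is refined by maximizing plain image correlation of the
  translation-aligned warp over a ±3 % log-scale grid with parabolic
  interpolation. The whitened phase-correlation *peak height* is noisy and
  multimodal in scale and is deliberately not used as the refinement
  objective.
* The final translation comes from phase correlation; its peak z-score
  against the correlation surface must exceed 8 (unrelated images score
  near the extreme-value level ~5), otherwise the estimate is refused —
  no silent fallback.

Residual distortion is summarized as the intensity-weighted RMS of per-block
phase-correlation displacements after alignment, reported in nm. On seeded
phantom batteries the median ratio error is well under 1 %, but the error
distribution is heavy-tailed: an occasional phantom with unfavorable
structure can miss by several percent while passing the z-score gate, which
is why batch analyses should use medians, as the tests do.

## Retention and the dilution exponent

Isotropic linear expansion by $E$ spreads retained molecules over $E^3$ the
volume, so conserved per-voxel intensity dilutes by $E^3$ (fourfold
expansion ⇒ 64-fold). `measure_retention()` undoes exactly that cubic
factor; whether to scale by the linear ratio or its cube was the one
genuinely open reading, and the cube is anchored to the stated 64-fold
dilution at fourfold expansion. The same exponent is used by the phantom
generator's `simulate_expansion()`, so generator and quantifier cannot
drift apart. Masks should sit strictly inside structures (use
`truth_mask(..., erode_px = )` on phantoms): PSF-blurred rims bias masked
means by a few percent otherwise.

In `simulate_expansion()` the *pre* composite is rendered with all
retentions forced to 1 (an unprocessed specimen), and the *post* composite
applies the per-structure `retention` fractions — homogenization losses
happen between the two acquisitions. Expansion is simulated in-plane per
slice (bilinear resampling by the ratio) while the intensity dilution stays
cubic; desk-scale stacks are too thin for meaningful z-resampling, and the
z geometry is carried by metadata.

## The phantom generator

`generate_tissue_phantom()` emulates a post-expansion brain-tissue field of
view: 497 nm pixels, nuclei as ellipsoids, blood vessels as
bounded-curvature random-walk tubes, neuronal somata as blobs each carrying
a nucleus, dendrites as thin branching filaments seeded at somata, and
chromosome-poor voids carved out of nuclei at reduced protein density. No
quantitative morphology statistics were available to match, so sizes,
counts and densities are stylized, exposed in `structure_spec()`, and
documented in `inst/extdata/phantom-template.yaml`; the defaults (nucleus
radius 9 µm, vessel radius 1.5 µm, soma radius 6 µm, dendrite half-width
0.5 µm in post-expansion units) are plausible for ~4×-expanded tissue.

The SRS composite follows the forward model
$\text{SRS} = \sum_k \rho_k r_k M_k + w_{\text{gel}}\,S + w_{\text{water}}$
(protein density × retention × structure map, plus a smooth hydrogel CH2
field and a uniform water O–H term), then lateral Gaussian PSF blur, then
noise. Setting both background weights to zero emulates full deuteration of
gel and water. Noise is Poisson–Gaussian by default (SRS detection is
shot-noise limited); a pure-Gaussian mode exists for analytic tests. Every
generator is a pure function of its spec including the seed.

What the phantoms deliberately do **not** emulate: Raman spectra and
spectral crosstalk beyond two scalar weights, optical sectioning and
aberrations, tissue scattering, lipid-channel contrast changes (there is no
lipid structure class), mosaic stitching, spine-scale (<200 nm) features.
Passing tests on phantoms therefore demonstrate algorithmic correctness
under the stated forward model, not performance on real tissue.

## Label-free prediction (U-Net)

The paired-training regime follows the standard recipe for label-free
fluorescence prediction: z-slices of
sequentially acquired fluorescence and SRS stacks become pixel-registered
2-D pairs; both channels are rolling-ball background subtracted and
percentile-normalized (1st–99.9th, per slice; the upstream normalization
formula is unstated, this is ours); the split into test and training is
1:3 by default and assigned per *volume*, never per patch, so no pixels
leak. Training samples random 128² patches in batches of 32 and runs Adam
at learning rate 0.001 on mean squared error. The full-scale regime of
50,000 training iterations at batch size 32 is implemented as 50,000
optimizer *steps* (one batch each): 50,000 literal passes over hundreds of
stacks would be implausible, and patch-based sampling has no natural epoch
anyway. The package default is a desk-scale 2,000 steps.

The network is a 2-D U-Net — double 3×3 conv + ReLU blocks, 2×2 max
pooling, bilinear ×2 upsampling, skip concatenation, linear 1×1 head —
written in RcppArmadillo (im2col + GEMM with full analytic backprop,
verified against finite differences at 4×10⁻⁸ relative error). No R deep
learning runtime is assumed. `depth` and `base_channels` shrink the model
for CPU-scale work; one model is trained per target channel (v-lectin,
v-DAPI, v-MAP2, v-NeuN), matching the per-channel upstream design.
Augmentation is off: whether flips/rotations were used upstream is
unstated.

Inference tiles each slice with overlapping tiles at stride tile/2, blended
by a smooth weight window that is *zero* within a margin (3/16 of the tile)
of any tile edge interior to the image and flat at edges flush with the
image border. Border-affected predictions therefore never contribute, and
tiled output matches whole-image inference to machine precision while still
being a smooth blend — the margin was sized to exceed the network's
receptive-field radius at the default desk depths.

Desk-scale problem sizes used by the test suite and chosen once for this
package: identity benchmark (8 phantom slices 96², patch 32, depth 1, base
8, 800 steps), vessel virtual-staining benchmark (8 slices 128², patch 48,
depth 2, base 8, 400 steps), rolling-ball radius 15 px on 96–128 px slices
(the classic radius-50 default is kept for full-size 512² frames at
0.497 µm/px). These reach held-out pooled r ≈ 0.99+ (identity) and ≈ 0.9
(vessels) in a few CPU-minutes; they demonstrate the pipeline, not
GPU-scale performance.

## Evaluation

`pearson()` implements the deviation-product formula directly with ground
truth as $x$ and prediction as $y$; a constant argument raises an
undefined-correlation error rather than silently returning 0. Whether
published correlation values were per-image means or pooled over test
pixels is not stated, so `evaluate_predictions()` reports both, with the
pooled value as the headline. The sparse-channel rule — scoring the vessel
channel only on images that contain genuine vessel signal, since a model
cannot predict background noise — is operationalized as: an image
participates iff the fraction of ground-truth pixels above its robust
threshold (`median + 3·MAD`) exceeds 0.1 %; both knobs are exposed.

`noise_robustness_curve()` degrades the *training* ground truth with
additive Gaussian noise of `sigma × sd(clean training targets)` — sigma is
expressed in units of the clean-image standard deviation — retrains from
the same seed, and evaluates against clean test ground truth. Accuracy
decreases as training ground truth gets noisier; on easy tasks (identity)
the decline is shallow, because the MSE-optimal predictor under
zero-mean target noise is unchanged and extra noise mainly slows
optimization — the informative regime is harder tasks at large sigma.

## Degenerate inputs and numerical tolerances

* `deconvolve_bead`: measured FWHM ≤ half the bead diameter is refused
  (not deconvolvable); ≤ the bare object width yields a no-root error;
  zero diameter returns the measurement unchanged. Root tolerances are
  10⁻⁴ nm (PSF) and 10⁻⁶ nm (FWHM crossing).
* `rolling_ball_subtract`: offsets outside the image are excluded from
  both erosion and dilation, so opening is defined up to the border
  without padding assumptions; a flat image maps to exactly zero.
* All-zero slices survive percentile normalization as all-zero (no
  division blowup); images smaller than one tile are reflect-padded at
  inference, never an error.
* Ties in `max` (bead plateaus, pooling argmax) resolve to the first
  index, fixed by iteration order, so outputs are bitwise reproducible.
* Maximum-intensity projections, generators, training, and inference are
  deterministic given seeds; training reproducibility is exact in
  single-threaded BLAS.

## Known limitations

* The Rayleigh constant convention is a documented choice (see above).
* Registration assumes a similarity transform; non-rigid gel distortion is
  only *reported* (block residual RMS), not corrected.
* The retention analysis needs background-subtracted inputs and interior
  masks; it does not model per-structure retention spectra.
* Phantom morphology is stylized; no claim of realism beyond the forward
  model is made, and no real-tissue benchmark is bundled (none is
  publicly deposited).
* The built-in U-Net is CPU-oriented; reproducing full-scale (50,000-step,
  512² frame) training is out of scope for this package.
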