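---
title: "Virtual imaging trials for an end-expandable fiber-bundle microendoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual imaging trials for an end-expandable fiber-bundle microendoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(brushsim)
```

## The problem

High-resolution microendoscopy (HRME) images epithelial nuclei through a
fused coherent fiber bundle after topical proflavine staining; the density,
size and pleomorphism of the bright nuclei are the cues that separate
neoplastic from non-neoplastic esophageal mucosa. A fused bundle, however,
covers well under a square millimetre of tissue, which makes surveying a
whole esophagus slow. An *end-expandable* ("brush") probe spreads the distal
fiber strands apart so the same number of fibers samples a much larger
area — at the cost of sampling it sparsely: each strand reports a single
intensity from its small footprint, and the tissue between strands is never
observed.

`brushsim` implements the computational side of evaluating such a probe
before any hardware exists: a *virtual imaging trial*. High-resolution
images are degraded through a parameterized model of sparse brush
acquisition, restored with a small convolutional super-resolution network
(SRCNN), and the restored images are scored with traditional image-quality
metrics and with reader-study statistics. Because clinical HRME images are
not redistributable, the package ships a synthetic phantom generator that
reproduces the statistical structure the pipeline relies on, so every stage
is testable end to end.

## The degradation model

The acquisition geometry has three micrometre-valued parameters, converted
to pixels at a physical pixel size of 2 µm (half-up rounding):

* **m** — fiber (ROI) diameter: the side of the m × m px footprint a strand
  actually averages over;
* **s** — inter-fiber distance: the side of the s × s px field-of-view (FOV)
  tile each strand is responsible for (m ≤ s);
* **d** — maximum deformation offset: each strand's footprint is displaced
  by independent integer offsets, uniform on {−d, …, +d} pixels per axis,
  modelling strand flexibility.

The image is tiled rectangularly from the top-left corner. In each FOV tile
the ROI is centered, shifted by the tile's sampled offset, and intersected
with the image bounds; the mean intensity over the surviving ROI pixels fills
the whole tile of the reconstituted low-resolution (LR) image. The model is
deliberately rectangular — a radial expansion geometry is a separate problem
and out of scope here.

Numerical and edge-case choices, all exercised by tests:

* Offsets are carried in micrometres in `degradation_params()` and converted
  with the same half-up rule as m and s.
* ROI centering uses `floor((extent − m)/2)`, biased at most half a pixel
  when the parity is odd, and is computed against the tile's *clipped*
  extent, so thin edge tiles of images not divisible by s still contain
  their ROI at d = 0.
* If an offset pushes a ROI entirely outside the image (possible only for
  aggressive d at the border), the tile falls back to the mean over its
  clipped FOV extent rather than failing.
* Offsets are resampled per image (seeded); `degrade(offsets = ...)` lets a
  caller freeze one simulated probe across a dataset instead.
* `dx` and `dy` share the single parameter d; the per-axis generalization
  would be mechanical.
* Sparse (non-sampled) pixels are tracked with a logical mask, not a
  sentinel intensity, so legitimate 0.0 values remain representable.

Structural guarantees (tested exhaustively against a brute-force per-tile
enumerator on small images, and as properties on random phantoms): the LR
image is constant within every tile, bounded by the input's range, a fixed
point on constant images, idempotent at d = 0, and exactly mean-preserving
when m = s on divisible dimensions.

## The phantom generator

`generate_phantom()` emulates what the pipeline needs from HRME data and
nothing more. Nuclei are placed by a homogeneous spatial Poisson process
with intensity `nucleus_density_per_mm2` over the field; each is a filled
ellipse with an equivalent-circle radius drawn from a truncated normal
(lower truncation 0.5 µm), uniform orientation, and eccentricity uniform on
[0, max]. Overlapping nuclei combine by maximum (not sum), which avoids
clipping artifacts in crowded neoplastic fields; the binary layer is then
smoothed with a 1 px Gaussian for anti-aliased edges, scaled between
background and nuclear intensity, and corrupted with additive zero-mean
Gaussian sensor noise. Everything is a pure function of the spec and its
seed.

The two class presets encode the diagnostic cues as relative differences:
the neoplastic preset triples the nuclear density (crowding), doubles the
radius SD and raises the eccentricity ceiling (pleomorphism). No published
quantitative densities exist for the two classes, so the absolute values
(150 vs 450 nuclei/mm², radius 6 vs 6.5 µm) are the package's own choice of
a plausible regime — they are simulation parameters, not biological claims.
Noise is additive Gaussian with one parameter rather than Poisson shot
noise; HRME sensor noise has never been characterized in a way that would
justify more structure.

What the phantoms deliberately do **not** model: photorealistic tissue
texture, illumination falloff, motion blur or defocus (the quality-control
failure modes of clinical series), optical point-spread functions, or fiber
cross-talk. Passing tests on phantoms therefore demonstrate correctness of
the *pipeline* — the degradation geometry, the training loop, the metrics —
not clinical performance on real mucosa.

An optional hexagonal comb overlay (`apply_comb_pattern()`) reproduces the
core-lattice artifact of fused bundles for testing the de-combing filter; it
is off by default in pipeline runs because preprocessing removes it
immediately anyway.

## Preprocessing

The standard chain is size standardization to 960 × 1280 px, a Gaussian
de-combing filter with σ = 2 px, and CLAHE with clip limit 0.005:

* "Standardization" is implemented as center-crop / reflect-pad rather than
  resampling, because the degradation geometry depends on the 2 µm/px scale
  and resampling would silently change it.
* The Gaussian uses reflect (symmetric) boundaries and a 4σ kernel
  truncation; with a normalized symmetric kernel this preserves the global
  mean exactly, and the filter is linear — both are asserted as properties.
* CLAHE conventions differ between implementations. Here the clip limit is
  the fraction of a tile's pixel count at which the normalized histogram is
  clipped — the 0–1 convention under which 0.005 is a sensible value. The
  computation is delegated to the Zuiderveld implementation in EBImage,
  converting the fraction to that implementation's bin-height multiple
  (`limit = clip_limit × bins`); the tile grid defaults to 8 × 8, the most
  widespread choice. Constant images are returned unchanged, and
  non-divisible image sizes are reflect-padded to a tile multiple and
  cropped back.
* The chain order is standardize → de-comb → CLAHE, applied before
  degradation; the SRCNN therefore trains on preprocessed targets.

## The SRCNN and its training protocol

The network is the classic three-layer SRCNN: 9×9/64 → leaky-ReLU → 1×1/32 →
leaky-ReLU → 5×5/1, with no nonlinearity after the last layer and 8129
trainable parameters for the default shapes. Choices the architecture
description leaves open:

* leaky-ReLU negative slope 0.2 (a common default, exposed in the config);
* "same" zero padding so SR outputs are pixel-comparable with HR targets;
* He-normal weight initialization, zero biases, seeded;
* inputs are [0, 1] floats with no mean subtraction.

Training minimizes pixelwise MSE with Adam over aligned random crops;
validation loss is computed once per epoch over the full validation patch
set and the returned weights are those of the best validation epoch. The
full-scale protocol (learning rate 1e-4, 300 epochs, batch 8, ten 512 × 512
patches per image) is the config default and is reachable, but the tested
path is a **reduced-scale protocol**: 40 training pairs of 128 × 128
phantoms, four 64 × 64 patches per image, 30 epochs at learning rate 1e-3.
The raised learning rate compensates for the tenfold-shorter schedule
(keeping learning-rate × epochs comparable); with it, the SR images beat
their LR counterparts in mean PSNR and SSIM on held-out phantoms, which is
the qualitative claim the package asserts. Because CPU floating-point
reduction order can vary, tests assert inequalities (SR better than LR),
never exact loss values.

There is no deep-learning-framework dependency: convolution forward and
weight-gradient passes are implemented in C++ (im2col plus BLAS GEMM via
RcppArmadillo), the input-gradient pass reuses the forward convolution with
flipped kernels, and Adam is a few lines of R. Correctness is established in
tests by a brute-force R convolution oracle and a finite-difference gradient
check, which is the same level of assurance a framework would give here at a
fraction of the footprint.

## Image quality and the parameter sweep

PSNR uses peak 1.0 on normalized floats (the dynamic range is an exposed
argument); identical images report `Inf`. SSIM uses the Wang et al.
defaults — 11 × 11 Gaussian window with σ = 1.5, K₁ = 0.01, K₂ = 0.03,
population (not sample) local moments — and crops the half-window border
before averaging, making the value boundary-independent. Both agree with an
independent reference implementation to better than 1e-6 on frozen random
pairs.

`run_sweep()` varies one degradation parameter at a time from a fixed
baseline (m = 4 µm, s = 8 µm, d = 0 — the demonstration configuration, made
configurable because the original study never states its fixed values
numerically): offset 0–10 µm, inter-fiber distance 4–24 µm, fiber diameter
4–12 µm. Infeasible points (m > s) are skipped with a warning. Published
sweep curves exist only as plots, so the package asserts trend directions —
mean LR PSNR non-increasing in s, SR not worse than LR beyond a small
tolerance — rather than digitized values.

## Reader-study statistics

Reader responses are binary neoplasia calls with a high/low confidence
grade, scored against a histopathology-style gold standard (positive class:
neoplastic). `confusion()` and `diagnostic_metrics()` are exact by
construction and tested against brute-force enumeration of all small 2×2
tables; undefined ratios (0/0) are reported as absent (`NA`), never as 0,
so pooled summaries cannot be silently biased. The unpaired t-test defaults
to the pooled-variance Student form (the usual reading of "unpaired
t-test"), with the Welch form behind a flag; degenerate zero-variance
comparisons return p = 1 when the means agree and error otherwise.

`equivalence_sample_size()` implements the two-proportion equal-variance
formulation without continuity correction,
n = ⌈(z₁₋α∕₂ + z₁₋β)² · 2p(1−p) / limit²⌉. The assumed proportion is an
explicit argument: a published n of this kind computed from "sample-based
variance estimates" cannot be reproduced without knowing the variance that
was assumed, and the package refuses to pretend otherwise.

The bundled `demo_gold_labels()` set is a synthetic 120-image panel with the
65%/35% neoplastic/non-neoplastic mix of a typical enriched reader study,
and `simulate_reader_responses()` draws seeded reader panels with chosen
per-reader accuracies, which is how the reporting pipeline is exercised
without human readers.

## Problem sizes used by the test suite

The suite runs the degradation oracle exhaustively on images up to 16 × 16
with all pixel geometries m ≤ s ≤ 8 and d ∈ {0, 1}; the monotone
information-loss check uses twenty 192 × 256 phantoms; the end-to-end
training check uses the reduced-scale protocol above (50 phantoms of
128 × 128, 30 epochs). These sizes were chosen so the whole suite, and the
`scripts/acceptance.R` summary run, complete comfortably on a single CPU
while still exercising every code path at realistic parameter values.

## Known limitations

* Rectangular tiling only; a radial/hexagonal expansion model is future
  work, as is any optical modelling (PSF, cross-talk, illumination).
* Phantoms are statistical, not photorealistic; conclusions about clinical
  reader performance require clinical images and human readers.
* The SRCNN is the simplest credible restoration network; stronger
  architectures would change the absolute sweep numbers, though not the
  harness.
* CPU training at full scale (300 epochs on 960 × 1280 images) is possible
  but slow; the package is tuned for the reduced-scale protocol.
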