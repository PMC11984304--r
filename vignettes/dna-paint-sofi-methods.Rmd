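---
title: "DNA-PAINT SOFI: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-PAINT SOFI: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(paintsofi)
```

# Overview

`paintsofi` models the full computational side of a high-throughput
super-resolution workflow built on exchangeable DNA labels: DNA-PAINT
blinking movies are simulated with programmable hybridization kinetics,
reconstructed by high-order (2-6) pixel-by-pixel cross-cumulant SOFI with
flattening, deconvolution and brightness linearization, optionally
localized molecule-by-molecule (SMLM) after a simulated buffer switch, and
quantified with decorrelation resolution analysis, jackknife SNR maps,
cross-section FWHM measurements and resolution-scaled error scores.
Multi-position acquisitions over a large phantom can be stitched into a
mosaic.

This vignette documents the underlying models, the estimators, the tunable
parameters, and the design decisions taken where the methods literature
leaves latitude.

# The blinking model

A docking site carries `n_repeat_motifs` concatenated binding motifs. Each
motif is an independent alternating renewal process:

* unbound dwells are exponential with mean `1 / per_site_binding_rate`
  (the binding rate is per motif and is taken as already proportional to
  the imager concentration, which is carried only as metadata);
* bound dwells are exponential with mean
  `mean_bound_time * destabilizer_on_time_factor`.

The `destabilizer_on_time_factor` (in (0, 1]) models a duplex-destabilizing
buffer additive such as ethylene carbonate that raises the dissociation
rate; repeat motifs multiply the binding-event frequency (five-fold for a
5x repeat versus a single motif, which the test suite verifies by Monte
Carlo). Simultaneous occupancy of distinct motifs is allowed by default
(`allow_simultaneous = TRUE`) and adds linearly in brightness; the
alternative (capped occupancy) is available because the experimental
literature does not settle whether simultaneous binding contributes.

Published rate constants for specific imager/docking pairs at specific
concentrations were not available to this package; the defaults
(`per_site_binding_rate = 2` events/s per motif, `mean_bound_time = 50` ms,
destabilizer factor 0.5 in the "fast" buffer) were chosen once as
representative of speed-optimized DNA-PAINT at nanomolar imager
concentrations with 10 ms frames: a five-motif site then shows roughly ten
binding events per second and a site-level duty cycle of about 0.2 emitter
equivalents, which produces the dense correlated blinking that high-order
SOFI needs. The "SMLM" buffer defaults
(`per_site_binding_rate = 0.05` /s, `mean_bound_time = 0.3` s, no
destabilizer, 100 ms frames) produce the sparse, bright, well-separated
events that single-emitter fitting needs.

# Movie rendering

Photon expectation per frame is computed with exact interval arithmetic:
each binding interval is intersected with each frame window, so the
occupancy series sums exactly to the bound time inside the movie (no
sub-frame discretization). The PSF is a 2-D Gaussian of configured FWHM
*integrated over each pixel area* (erf differences), not sampled at pixel
centres; centre sampling aliases visibly once the FWHM approaches two
pixels and distorts the shapes of high-order cumulants, which are PSF
powers. Background is uniform (the diffusive-imager sea), scaled by the
illumination mode (TIRF 1x, HILO 2x, EPI 5x as a package convention for the
loss of optical sectioning). Camera counts are
`round(gain * Poisson(expected) + N(0, read_noise) + offset)`, clipped at
zero, emulating an sCMOS camera with uniform gain.

Photobleaching is absent by default: exchangeable imagers are continuously
replenished from the buffer, which is precisely why DNA-PAINT suits
high-order SOFI.

Randomness follows a strict seeding contract: one master seed; each site
draws its binding trace from a child stream derived from the master seed
and the site id, and the camera noise uses a separate child stream.
Adding a site to a phantom therefore does not perturb any other site's
trace, and identical configurations give byte-identical movies after file
round-trips.

Coordinates: the sample frame is in nanometres with the origin at the
field corner; camera pixel (0,0) covers `[0, pixel_size)^2`; emitter
positions are continuous.

# Cumulant estimation

The order-n joint cumulant of pixel time series is evaluated through the
set-partition formula applied to mean-subtracted series, so only
partitions with all blocks of size at least two contribute (41 such
partitions at order six). All moment estimators use the biased 1/T
normalization, the standard convention in fluctuation imaging, so images
are comparable across orders. Only zero time lag is used: frame-integrated
DNA-PAINT blinking at these rates decorrelates within a frame or two, and
zero lag keeps the estimator free of lag-selection choices.

## Virtual pixels

Cross-cumulants of n distinct (not necessarily different) pixels are
attributed to the centroid of the participating pixels, refining the
camera grid n-fold. For a Gaussian PSF the emitter-independent prefactor
of such a combination is the distance factor
`exp(-sum_i |r_i - rbar|^2 / (2 sigma_eff^2))`.

Two implementation details matter:

* **Combination choice.** Among all n-pixel multisets with the required
  centroid, the summed squared distance to the centroid separates over x
  and y, and the integer multiset minimizing it along one axis is "k
  pixels at base+1, n-k at base" for lattice residue k - a closed form, no
  search. Pairing the sorted x multiset with the sorted y multiset
  ascending-ascending is the lexicographic tie-break. This combination
  maximizes the distance factor and hence the virtual pixel's SNR, and is
  deterministic. Integer lattice points use the degenerate combination
  (one pixel repeated n times) and exactly reproduce the auto-cumulant.
* **Effective PSF width.** Rendered pixel values are box-integrated
  Gaussians, so the Gaussian factorization that defines the distance
  factor holds for the effective width
  `sigma_eff^2 = sigma_psf^2 + 1/12` (camera pixels), not the optical
  sigma. Using `sigma_eff` reduces the residual lattice-parity pattern of
  the flattened image to the percent level for typical sampling.

Fine-lattice points whose combination would need a pixel beyond the frame
edge are flagged missing and filled during flattening.

## Subsequences and drift

Movies are processed in consecutive blocks of 1000 frames (a movie shorter
than 1000 frames forms a single full-length block; remainder frames beyond
the last complete block are dropped so all blocks share the same estimator
variance). Block images are registered to the first block by
cross-correlation with parabolic sub-pixel refinement and averaged. Shifts
are estimated on the order-2 block images, which have by far the best SNR,
and rescaled to each order's lattice. Flattening is applied after
drift-corrected combination: the distance-factor pattern is
shift-invariant, while flattening first would interpolate missing edge
points before registration has had the chance to move them, so the chosen
order loses nothing and keeps the combination linear.

# Flattening

After division by the distance factors, two residual lattice-periodic
patterns remain in real (noisy) data, both originating from combinations
with repeated pixels, which are the only ones that pick up shot- and
read-noise cumulants:

1. an additive n-periodic comb visible in low-signal regions - removed by
   subtracting, per parity class, the median offset against a smoothed
   reference estimated over the darkest quartile;
2. a signal-proportional comb - removed by dividing each parity class by a
   locally smoothed gain field relative to a parity-agnostic reference
   smoothed over the same physical window.

Missing lattice points are then filled by local interpolation, and the
result is flagged so that flattening is idempotent. Without step (1)-(2)
the comb leaks spectral energy near the lattice frequencies and corrupts
decorrelation resolution estimates at exactly the radii where
super-resolution content is being claimed.

# Deconvolution and brightness linearization

Richardson-Lucy deconvolution runs for a fixed iteration count (default
10) with a Gaussian kernel. The default kernel FWHM is 4.2 camera pixels
regardless of lattice oversampling (`deconv_fwhm_px`, i.e.
`4.2 * oversampling` lattice units), matching common practice for
camera-scale PSF approximations. Because the order-n cumulant PSF is
`psf_fwhm / sqrt(n)`, a fixed camera-scale kernel over-sharpens high
orders on fine lattices; `deconv_fwhm_mode = "matched"` instead derives
the kernel per order from the movie metadata as `psf_fwhm / sqrt(n)`
camera pixels. The resolution and two-point analyses in the test suite use
the matched mode, since they compare orders against each other and an
intentionally mismatched kernel would confound the comparison; the fixed
value remains the default for parity with common SOFI processing.

Negative cumulant values - legitimate for odd orders and for order 4 at
duty cycles above `1/2 - 1/(2 sqrt(3)) ~ 0.211` - are clipped to zero only
for the RL step; the signed flattened cumulant is retained in the result
object for diagnostics. RL borders are handled by reflective padding.

Brightness linearization applies the signed n-th root after
deconvolution, so emitter brightness enters the final image linearly
rather than to the n-th power (a factor-8 brightness pair differs by
512x in a raw third-order image and by ~8x after linearization). An
optional re-convolution with a Gaussian of `fwhm / sqrt(order)` is
provided but off by default, since the processing chain being mirrored
lists only deconvolution and linearization.

# Quality control

* **Decorrelation resolution.** The image spectrum is cross-correlated
  with its phase-normalized self under binary masks of 100 equidistant
  radii, for the raw image and 20 Gaussian high-pass strengths
  (log-spaced widths 0.05-1 in normalized frequency); borders are
  apodized with a 10% cosine ramp. Each curve contributes its
  highest-frequency interior local maximum with prominence above 0.05
  over the following tail (the reference implementation leaves the
  significance rule unstated; 0.05 is this package's stated default);
  the cutoff is the maximum across curves, falling back to the global
  maximum of the raw curve when no interior peak exists (pure white noise
  then correctly reports ~2 pixels). Resolution is
  `2 * pixel / cutoff`.
* **Jackknife SNR.** The N leave-one-frame-out cumulant images are
  produced from updatable power sums (per-pixel series are centred first
  to avoid catastrophic cancellation against the camera offset), and
  `sigma = sqrt(((N-1)/N) * sum (I_n - mean)^2)` - the standard jackknife
  estimator including the (N-1)/N factor, adopted as the canonical form of
  the resampling method. For order 1 this reproduces `s / sqrt(N)`
  exactly, which the tests check to 1e-8. The map is computed on the
  auto-cumulant image (no deconvolution), keeping the estimator linear in
  the moment accumulators; SNR of the postprocessed image would depend on
  the deconvolution's noise propagation and is deliberately out of scope.
* **Cross-section FWHM.** Profiles are sampled by bilinear interpolation
  at a quarter-pixel spacing; the baseline is the mean of the outer 20% of
  the profile (the normalization step needs *some* baseline convention;
  this one is stated and tested); the FWHM comes from linear interpolation
  of the half-maximum crossings and is reported in nm using the lattice
  pixel pitch, so SOFI's pixel-size reduction is accounted for.
* **RSP/RSE.** The super-resolution image is block-averaged onto the
  reference grid, registered, blurred with a Gaussian resolution scaling
  function whose FWHM is optimized over 0.5-20 pixels (bounded scalar
  minimization; the bounds are this package's choice), with the affine
  intensity map solved in closed form; the minimized RMSE (RSE) and the
  Pearson correlation at the optimum (RSP) are reported. The intended
  reference is the temporal standard-deviation projection of the raw
  movie, which equals the square root of the order-2 auto-cumulant.

# SMLM branch

Detection uses a difference-of-Gaussians band-pass (equivalent defaults to
the common wavelet cascade; no claim of bit-parity) with an
8-connected-local-maximum threshold of 3 robust SDs. Sub-pixel fitting is
weighted least squares (weights `1/max(counts, 1)`) of a pixel-integrated
Gaussian with constant background on a 9x9 window (fit radius 4, initial
sigma 1.6 px); fits that do not converge within 50 iterations are dropped
and counted. Uncertainty is the Thompson-style lateral precision
`sqrt((s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2))` with `b` the
background noise SD in photons (the square root of the fitted Poisson
background level); the uncertainty filter threshold (default 15) is
interpreted in nanometres, the localization table's native unit.
Drift correction renders 25 nm histograms of twentieths of the
acquisition, estimates block shifts against the first block by
cross-correlation with sub-pixel refinement, and interpolates linearly
per frame with linear extrapolation beyond the first and last block
centres (constant extrapolation would leave a systematic ramp error of
half a block at both ends). Rendering uses 2x2 averaged shifted
histograms at 5x magnification with edge folding, so the rendered mass
equals the record count exactly.

# Mosaics

Grid plans follow the multiposition convention: raster order, nominal
steps of `tile * (1 - overlap)`. Simulated acquisitions add Gaussian stage
jitter (default SD 2 px) to the nominal offsets - noiseless stage motion
would leave the stitching refinement untested - and re-render each tile
from the phantom restricted to its true window, with independent blinking
per acquisition since tiles are imaged sequentially. Stitching refines
each tile against the composited canvas by masked-smoothed normalized
cross-correlation (integer search) followed by a gradient-based
(Lucas-Kanade style) sub-pixel stage with an affine intensity term, then
runs one leave-one-out re-registration pass over all tiles to break the
chain-error accumulation of the raster pass, and composites with linear
feather blending. Overlaps whose best correlation stays below 0.5 fall
back to the nominal offset with a warning. Tiles cut exactly from one
image stitch back to it exactly (the sub-pixel stage converges to zero on
identical content).

Registration accuracy depends on there being structure in every overlap
strip; the package provides a line-lattice phantom
(`make_line_lattice_phantom`) whose crossing line families guarantee
coverage of all tile boundaries, which random filament phantoms do not.

# What the simulations do and do not emulate

The generator reproduces the statistical structure that the estimators
consume: renewal blinking with programmable rates, multi-emitter
superposition, Poisson photon statistics, Gaussian read noise, uniform
diffusive background, stage jitter. It does not emulate out-of-focus
cellular background structure (an optional wide-Gaussian structural
background exists but is off by default), dipole emission effects,
sCMOS pixel-dependent gain/read-noise maps, 3-D PSFs, imager depletion,
or photophysical dark states of the dyes. Passing tests therefore
demonstrate the correctness of the estimators and the internal
consistency of the pipeline under the stated model - not performance on
any particular microscope's data.

# Problem sizes

The shipped tests and the acceptance script use sizes chosen to exercise
every code path at meaningful statistics: 64 x 64 px, 5000-frame movies
for the resolution-ordering analysis (about 2000 docking sites along four
filaments); 1-2 x 10^6-sample series for closed-form cumulant checks;
2 x 3 mosaics of 96 px tiles, 500 frames each; a few hundred repeated fits for
localization precision. Larger fields and longer movies scale linearly in
time and memory (the order-n cross-cumulant engine is O(T 2^n) per
virtual pixel).

# Known limitations

* Cumulant orders above six are not implemented (partition enumeration is
  general, but the virtual-pixel engine caps at n = 6).
* The jackknife SNR covers auto-cumulant orders 1-4 only.
* The RL deconvolution assumes a spatially invariant Gaussian PSF.
* Stitching estimates pure translations; rotation and scale errors are
  out of scope.
* The decorrelation significance threshold (0.05) is a fixed default, not
  adaptive; heavily structured noise can in principle still defeat the
  peak rule.
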