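# paintsofi

Super-resolution optical fluctuation imaging (SOFI) turns the blinking of
fluorescent labels into resolution: the order-n temporal cumulant of the
pixel intensity fluctuations carries the point-spread function raised to
the n-th power, so a Gaussian PSF narrows by sqrt(n) before deconvolution
and by up to n after it. DNA-PAINT supplies ideal blinking for this —
imager oligos transiently hybridize to target-bound docking strands, so
the on/off kinetics are programmable through sequence design (repeat-motif
docking strands multiply the event frequency), imager concentration
(shortens off-times) and duplex-destabilizing buffer additives (shorten
on-times), and there is no photobleaching because imagers are replenished
from the buffer.

`paintsofi` implements the full computational workflow for tuning and
exploiting this combination, for microscopists and methods developers who
want a controlled, fully synthetic testbed:

* a **DNA-PAINT blinking simulator**: docking-site phantoms (filaments,
  point pairs, line lattices, uniform fields), per-motif alternating
  renewal kinetics, pixel-integrated Gaussian PSF rendering, diffusive
  background, sCMOS noise, strict per-site seeding;
* a **cross-cumulant SOFI engine** (orders 2–6): zero-lag joint cumulants
  via the set-partition formula on an n-fold oversampled virtual-pixel
  lattice with closed-form combination selection and Gaussian distance
  factors, 1000-frame subsequence splitting, cross-correlation drift
  correction, flattening, Richardson–Lucy deconvolution (Gaussian kernel,
  FWHM 4.2 camera px, 10 iterations by default) and brightness
  linearization (signed n-th root);
* a **minimal SMLM branch**: DoG detection, weighted-least-squares
  integrated-Gaussian fitting (radius 4 px, initial sigma 1.6 px),
  Thompson uncertainty with a 15 nm filter, cross-correlation drift
  correction, 5x averaged-shifted-histogram rendering, ThunderSTORM-style
  CSV I/O;
* **quality control**: image decorrelation resolution (100 mask radii, 20
  high-pass filters), leave-one-frame-out jackknife SNR maps,
  cross-section FWHM, and RSP/RSE artifact scores against a temporal
  standard-deviation reference;
* **mosaics**: multi-position grid simulation with stage jitter and
  feather-blended stitching with sub-pixel registration.

## Worked example

Simulate a microtubule-like phantom under a speed-optimized buffer
(5x repeat motifs, destabilizer factor 0.5, 10 ms frames), reconstruct
SOFI orders 2 and 4, and estimate the resolution of each image:

```r
library(paintsofi)

kin <- kinetic_params(per_site_binding_rate = 2,    # events/s per motif
                      mean_bound_time = 0.05,       # 50 ms on-time
                      n_repeat_motifs = 5,
                      destabilizer_on_time_factor = 0.5)
ph  <- make_filament_phantom(4, extent_nm = c(6400, 6400),
                             site_linear_density = 0.05, kinetics = kin,
                             seed = 3)
opt <- optics_camera(pixel_size_nm = 100, psf_fwhm_nm = 320,
                     frame_time_s = 0.01, n_frames = 5000, seed = 11)
movie <- render_movie(ph, opt)

res <- sofi_pipeline(movie, sofi_config(orders = c(2, 4),
                                        deconv_fwhm_mode = "matched"))

decorrelation_resolution(mean_image(movie), 100)
#> <resolution_estimate> 360.0 nm (cutoff 0.556, 100.00 nm/px)
decorrelation_resolution(res$orders[["2"]]$image,
                         res$orders[["2"]]$pixel_size_nm)
#> <resolution_estimate> 210.6 nm (cutoff 0.475, 50.00 nm/px)
decorrelation_resolution(res$orders[["4"]]$image,
                         res$orders[["4"]]$pixel_size_nm)
#> <resolution_estimate> 183.3 nm (cutoff 0.273, 25.00 nm/px)
```

The diffraction-limited average image resolves ~360 nm; the second-order
reconstruction improves this to ~211 nm and the fourth order to ~183 nm —
the monotone order-to-order gain that makes the fast-screening workflow
worthwhile. Switching the same phantom to a sparse SMLM buffer and
localizing instead:

```r
kin_smlm <- kinetic_params(per_site_binding_rate = 0.05,
                           mean_bound_time = 0.3)
ph$kinetics <- kin_smlm
movie_smlm <- render_movie(ph, optics_camera(frame_time_s = 0.1,
                                             n_frames = 2000,
                                             photons_per_bound_imager_per_s = 5e4,
                                             seed = 12))
locs <- filter_and_drift_correct(localize_movie(movie_smlm), 15)
ash  <- render_ash(locs, magnification = 5)
```

A command-line entry point (`exec/paintsofi`) wraps the same functions:
`paintsofi workflow` runs the full screen-then-zoom demo (dense-kinetics
movie → SOFI orders → simulated buffer switch → SMLM → QC report);
`simulate`, `sofi`, `localize`, `metrics` and `stitch` expose the
individual stages. Every run writes a log and the fully resolved
configuration.

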