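## Hybridization kinetics and acquisition parameter containers.

#' DNA-PAINT hybridization kinetics of a docking site
#'
#' A docking site carries `n_repeat_motifs` concatenated binding motifs
#' (1 for a P3-like strand, 5 for a 5xR1-like repeat strand), each an
#' independent two-state renewal process: unbound dwells are exponential with
#' mean `1 / per_site_binding_rate` (the rate is per motif and is assumed
#' already proportional to the imager concentration), bound dwells are
#' exponential with mean `mean_bound_time * destabilizer_on_time_factor`.
#' The destabilizer factor models a duplex-destabilizing buffer additive
#' (ethylene carbonate) that shortens on-times.
#'
#' @param per_site_binding_rate binding events per second per motif (> 0).
#' @param mean_bound_time mean bound dwell time in seconds (> 0).
#' @param n_repeat_motifs integer >= 1, number of concatenated motifs.
#' @param destabilizer_on_time_factor multiplier in (0, 1] applied to
#'   `mean_bound_time`.
#' @param imager_concentration_nM metadata only; the binding rate is taken
#'   as already scaled to the working concentration.
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(per_site_binding_rate = 2,
                           mean_bound_time = 0.05,
                           n_repeat_motifs = 1L,
                           destabilizer_on_time_factor = 1,
                           imager_concentration_nM = NA_real_) {
  if (!is.finite(per_site_binding_rate) || per_site_binding_rate <= 0)
    stop("per_site_binding_rate must be finite and > 0")
  if (!is.finite(mean_bound_time) || mean_bound_time <= 0)
    stop("mean_bound_time must be finite and > 0")
  if (n_repeat_motifs < 1) stop("n_repeat_motifs must be >= 1")
  if (destabilizer_on_time_factor <= 0 || destabilizer_on_time_factor > 1)
    stop("destabilizer_on_time_factor must be in (0, 1]")
  structure(list(per_site_binding_rate = per_site_binding_rate,
                 mean_bound_time = mean_bound_time,
                 n_repeat_motifs = as.integer(n_repeat_motifs),
                 destabilizer_on_time_factor = destabilizer_on_time_factor,
                 imager_concentration_nM = imager_concentration_nM),
            class = "kinetic_params")
}

# Background scaling of the illumination modes relative to TIRF sectioning.
.illumination_background_factor <- c(TIRF = 1, HILO = 2, EPI = 5)

#' Optics and camera model for movie rendering
#'
#' Describes the 2-D Gaussian PSF, the frame clock, the emitter brightness,
#' the uniform diffusive-imager background (scaled by the illumination-mode
#' sectioning factor: TIRF 1x, HILO 2x, EPI 5x) and an sCMOS noise model
#' (per-pixel Poisson shot noise, Gaussian read noise, gain and offset).
#'
#' @param pixel_size_nm camera pixel size in sample-space nm.
#' @param psf_fwhm_nm PSF full width at half maximum in nm (> pixel size).
#' @param frame_time_s integration time per frame in seconds.
#' @param n_frames number of frames to record.
#' @param photons_per_bound_imager_per_s detected photon rate of one bound
#'   imager.
#' @param background_photons_per_pixel_per_frame mean background photons per
#'   pixel per frame under TIRF; multiplied by the illumination-mode factor.
#' @param illumination_mode one of "TIRF", "HILO", "EPI".
#' @param camera_gain counts per photon.
#' @param camera_offset baseline counts.
#' @param read_noise_sd read noise standard deviation in counts.
#' @param seed RNG seed for rendering; per-site and noise child streams are
#'   derived deterministically from it.
#' @return object of class `optics_camera`.
#' @export
optics_camera <- function(pixel_size_nm = 100,
                          psf_fwhm_nm = 320,
                          frame_time_s = 0.01,
                          n_frames = 1000L,
                          photons_per_bound_imager_per_s = 3e5,
                          background_photons_per_pixel_per_frame = 20,
                          illumination_mode = c("TIRF", "HILO", "EPI"),
                          camera_gain = 1,
                          camera_offset = 100,
                          read_noise_sd = 1.6,
                          seed = 1L) {
  illumination_mode <- match.arg(illumination_mode)
  vals <- c(pixel_size_nm, psf_fwhm_nm, frame_time_s, n_frames,
            photons_per_bound_imager_per_s, camera_gain)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical quantities must be finite and > 0")
  if (camera_offset < 0) stop("camera_offset must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (background_photons_per_pixel_per_frame < 0)
    stop("background must be >= 0")
  if (psf_fwhm_nm <= pixel_size_nm)
    stop("psf_fwhm_nm must exceed pixel_size_nm (the PSF must be sampled)")
  structure(list(
    pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
    frame_time_s = frame_time_s, n_frames = as.integer(n_frames),
    photons_per_bound_imager_per_s = photons_per_bound_imager_per_s,
    background_photons_per_pixel_per_frame = background_photons_per_pixel_per_frame,
    illumination_mode = illumination_mode,
    camera_gain = camera_gain, camera_offset = camera_offset,
    read_noise_sd = read_noise_sd, seed = as.integer(seed)),
    class = "optics_camera")
}

# Deterministic child seed derivation: one master seed, one stream per
# (purpose, index) pair, so adding a site never perturbs other sites' traces.
child_seed <- function(master, purpose, index = 0L) {
  offs <- switch(purpose, site = 104729, noise = 15485863, tile = 32452843,
                 stop("unknown seed purpose"))
  as.integer((as.double(master) * 2654435761 + offs * (as.double(index) + 1)) %%
               2147483647)
}
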