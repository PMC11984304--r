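## Declarative run configuration: a single YAML file describing the phantom,
## kinetics, optics, SOFI settings, SMLM settings and seeds. Unknown keys
## are rejected; every run logs the fully resolved configuration.

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "paintsofi_out",
    phantom = list(kind = "filaments", n_filaments = 3,
                   extent_nm = c(4800, 4800), site_linear_density = 0.05,
                   curvature = 0.15, separation_nm = 200),
    kinetics = list(per_site_binding_rate = 2, mean_bound_time = 0.05,
                    n_repeat_motifs = 5, destabilizer_on_time_factor = 0.5,
                    imager_concentration_nM = 20),
    smlm_kinetics = list(per_site_binding_rate = 0.05, mean_bound_time = 0.3,
                         n_repeat_motifs = 1,
                         destabilizer_on_time_factor = 1,
                         imager_concentration_nM = 0.5),
    optics = list(pixel_size_nm = 100, psf_fwhm_nm = 320,
                  frame_time_s = 0.01, n_frames = 600,
                  photons_per_bound_imager_per_s = 3e5,
                  background_photons_per_pixel_per_frame = 20,
                  illumination_mode = "TIRF", camera_gain = 1,
                  camera_offset = 100, read_noise_sd = 1.6),
    smlm_optics = list(frame_time_s = 0.1, n_frames = 1200,
                       photons_per_bound_imager_per_s = 5e4,
                       background_photons_per_pixel_per_frame = 10),
    sofi = list(orders = c(2, 3, 4, 5, 6), deconv_fwhm_px = 4.2,
                deconv_iterations = 10, deconv_fwhm_mode = "fixed",
                linearize = TRUE, block_length = 1000, register = TRUE),
    smlm = list(threshold_factor = 3, fit_radius = 4, init_sigma = 1.6,
                max_uncertainty_nm = 15, ash_magnification = 5.0),
    metrics = list(decorrelation = TRUE, jackknife_order = 2,
                   jackknife = FALSE))
}

#' Read and validate a run configuration
#'
#' Parses a YAML configuration, validates every key against the known
#' schema (unknown keys are an error) and fills missing entries from the
#' package defaults.
#'
#' @param path YAML file path, or NULL for the packaged defaults.
#' @return the resolved configuration list (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  if (is.null(path)) {
    cfg <- defaults
  } else {
    user <- yaml::read_yaml(path)
    check_keys <- function(u, d, prefix = "") {
      bad <- setdiff(names(u), names(d))
      if (length(bad))
        stop(sprintf("unknown configuration key(s): %s",
                     paste0(prefix, bad, collapse = ", ")))
      for (k in names(u)) {
        if (is.list(u[[k]]) && is.list(d[[k]]))
          check_keys(u[[k]], d[[k]], paste0(prefix, k, "."))
      }
    }
    check_keys(user, defaults)
    cfg <- modifyList(defaults, user)
  }
  structure(cfg, class = c("run_config", "list"))
}

resolved_config_text <- function(cfg) {
  yaml::as.yaml(unclass(cfg))
}

build_phantom_from_config <- function(cfg, kinetics) {
  p <- cfg$phantom
  switch(p$kind,
    filaments = make_filament_phantom(
      p$n_filaments, extent_nm = unlist(p$extent_nm),
      site_linear_density = p$site_linear_density, kinetics = kinetics,
      curvature = p$curvature, seed = cfg$seed),
    point_pair = make_point_pair_phantom(
      p$separation_nm, kinetics = kinetics,
      extent_nm = unlist(p$extent_nm)),
    stop(sprintf("unknown phantom kind '%s'", p$kind)))
}

kinetics_from_config <- function(k) {
  kinetic_params(per_site_binding_rate = k$per_site_binding_rate,
                 mean_bound_time = k$mean_bound_time,
                 n_repeat_motifs = k$n_repeat_motifs,
                 destabilizer_on_time_factor = k$destabilizer_on_time_factor,
                 imager_concentration_nM = k$imager_concentration_nM)
}

optics_from_config <- function(o, seed, overrides = list()) {
  o <- modifyList(o, overrides)
  optics_camera(pixel_size_nm = o$pixel_size_nm,
                psf_fwhm_nm = o$psf_fwhm_nm,
                frame_time_s = o$frame_time_s, n_frames = o$n_frames,
                photons_per_bound_imager_per_s =
                  o$photons_per_bound_imager_per_s,
                background_photons_per_pixel_per_frame =
                  o$background_photons_per_pixel_per_frame,
                illumination_mode = o$illumination_mode,
                camera_gain = o$camera_gain,
                camera_offset = o$camera_offset,
                read_noise_sd = o$read_noise_sd, seed = seed)
}

sofi_config_from_config <- function(s) {
  sofi_config(orders = as.integer(unlist(s$orders)),
              deconv_fwhm_px = s$deconv_fwhm_px,
              deconv_iterations = s$deconv_iterations,
              deconv_fwhm_mode = s$deconv_fwhm_mode,
              linearize = s$linearize,
              block_length = s$block_length,
              register = s$register)
}
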