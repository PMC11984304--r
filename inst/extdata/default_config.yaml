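# Default run configuration for the paintsofi CLI. Every field shown here
# can be overridden from a user config; unknown keys are rejected.
seed: 1
output_dir: paintsofi_out
phantom:
  kind: filaments          # filaments | point_pair
  n_filaments: 3
  extent_nm: [4800, 4800]
  site_linear_density: 0.05   # sites per nm of filament
  curvature: 0.15
  separation_nm: 200          # used by the point_pair kind
kinetics:                     # SOFI-optimized buffer (fast blinking)
  per_site_binding_rate: 2    # events/s per motif
  mean_bound_time: 0.05       # s
  n_repeat_motifs: 5
  destabilizer_on_time_factor: 0.5
  imager_concentration_nM: 20
smlm_kinetics:                # sparse buffer after the switch
  per_site_binding_rate: 0.05
  mean_bound_time: 0.3
  n_repeat_motifs: 1
  destabilizer_on_time_factor: 1
  imager_concentration_nM: 0.5
optics:
  pixel_size_nm: 100
  psf_fwhm_nm: 320
  frame_time_s: 0.01          # 100 Hz for the fast screen
  n_frames: 600
  photons_per_bound_imager_per_s: 300000
  background_photons_per_pixel_per_frame: 20
  illumination_mode: TIRF
  camera_gain: 1
  camera_offset: 100
  read_noise_sd: 1.6
smlm_optics:                  # overrides applied for the SMLM acquisition
  frame_time_s: 0.1           # 10 Hz
  n_frames: 1200
  photons_per_bound_imager_per_s: 50000
  background_photons_per_pixel_per_frame: 10
sofi:
  orders: [2, 3, 4, 5, 6]
  deconv_fwhm_px: 4.2
  deconv_iterations: 10
  deconv_fwhm_mode: fixed     # fixed | matched
  linearize: true
  block_length: 1000
  register: true
smlm:
  threshold_factor: 3
  fit_radius: 4
  init_sigma: 1.6
  max_uncertainty_nm: 15
  ash_magnification: 5.0
metrics:
  decorrelation: true
  jackknife: false
  jackknife_order: 2
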