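# Shared fixtures and independent oracles for the test suite.

# Brute-force joint-cumulant oracle: enumerates set partitions by recursive
# insertion of elements into existing blocks (a different algorithm from the
# package's restricted-growth-string enumeration) and evaluates RAW
# (uncentred) moments over all partitions, including singletons. Shares no
# helpers with the implementation.
oracle_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- oracle_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

oracle_joint_cumulant <- function(xmat) {
  n <- ncol(xmat)
  total <- 0
  for (p in oracle_partitions(n)) {
    b <- length(p)
    term <- (-1)^(b - 1) * factorial(b - 1)
    for (blk in p)
      term <- term * mean(apply(xmat[, blk, drop = FALSE], 1L, prod))
    total <- total + term
  }
  total
}

# SOFI-optimized buffer conditions: repeat-motif docking strand, high imager
# concentration, duplex destabilizer.
dense_kinetics <- function() {
  kinetic_params(per_site_binding_rate = 2, mean_bound_time = 0.05,
                 n_repeat_motifs = 5L, destabilizer_on_time_factor = 0.5)
}

# SMLM buffer: low imager concentration, single motif, long frames.
sparse_kinetics <- function() {
  kinetic_params(per_site_binding_rate = 0.05, mean_bound_time = 0.3,
                 n_repeat_motifs = 1L)
}

# One blinking emitter centred in a small clean field (negligible background,
# no read noise) - auto-cumulant images of this are pure PSF powers.
single_emitter_movie <- function(n_frames = 1500, psf_fwhm_nm = 320,
                                 seed = 7, extent_nm = c(2100, 2100)) {
  kin <- kinetic_params(per_site_binding_rate = 2, mean_bound_time = 0.05)
  ph <- make_point_pair_phantom(0, kin, extent_nm = extent_nm)
  opt <- optics_camera(psf_fwhm_nm = psf_fwhm_nm, n_frames = n_frames,
                       background_photons_per_pixel_per_frame = 0.01,
                       read_noise_sd = 0, camera_offset = 0, seed = seed)
  render_movie(ph, opt, noise = FALSE)
}

# Relative dip between two peaks along a horizontal profile:
# 1 - valley / mean(peaks); ~0 when the pair is unresolved.
profile_dip <- function(img, pixel_size_nm, y_nm, x0_nm, x1_nm) {
  xs <- seq(x0_nm, x1_nm, by = pixel_size_nm / 4) / pixel_size_nm
  p <- paintsofi:::bilinear_sample(img, rep(y_nm / pixel_size_nm,
                                            length(xs)) + 0.5, xs + 0.5)
  p <- p - min(p)
  n <- length(p)
  mid <- round(n / 2)
  li <- which.max(p[1:mid])
  ri <- mid + which.max(p[(mid + 1):n])
  valley <- min(p[li:ri])
  1 - valley / mean(c(p[li], p[ri]))
}

# Monte-Carlo standard error of a cumulant estimate from chunked series.
chunked_se <- function(x, order, n_chunks = 100) {
  chunks <- split(x, rep(seq_len(n_chunks), each = length(x) / n_chunks))
  ests <- vapply(chunks, joint_cumulant, numeric(1), order = order)
  sd(ests) / sqrt(n_chunks)
}
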