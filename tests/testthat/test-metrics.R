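# QC metrics: decorrelation resolution, jackknife SNR, FWHM, RSP/RSE.

test_that("decorrelation finds a synthetic band limit and is scale
           invariant", {
  set.seed(3)
  # white noise restricted to normalized frequencies below r0 = 0.5
  n <- 128
  wn <- matrix(rnorm(n * n), n)
  f <- fft(wn)
  fy <- ((seq_len(n) - 1 + n %/% 2) %% n - n %/% 2) / (n / 2)
  rad <- sqrt(outer(fy^2, fy^2, "+"))
  f[rad > 0.5] <- 0
  band <- Re(fft(f, inverse = TRUE)) / n^2
  est <- decorrelation_resolution(band, pixel_size_nm = 100)
  expect_lt(abs(est$cutoff - 0.5) / 0.5, 0.10)
  expect_equal(est$resolution_nm, 2 * 100 / est$cutoff)

  # doubling the pixel size while halving the grid keeps the nm resolution
  down <- paintsofi:::block_average(band, 2)
  est2 <- decorrelation_resolution(down, pixel_size_nm = 200)
  expect_lt(abs(est2$resolution_nm - est$resolution_nm) / est$resolution_nm,
            0.15)
})

test_that("pure white noise decorrelates only at the Nyquist edge", {
  set.seed(4)
  wn <- matrix(rnorm(96 * 96), 96)
  est <- decorrelation_resolution(wn, pixel_size_nm = 100)
  expect_gt(est$cutoff, 0.9)
  expect_error(decorrelation_resolution(matrix(1, 96, 96), 100),
               "no spectral content")
  expect_error(decorrelation_resolution(wn[1:32, ], 100), "64")
})

test_that("jackknife of the mean image equals the closed-form standard
           error", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(2, extent_nm = c(2400, 2400),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 2)
  m <- render_movie(ph, optics_camera(n_frames = 200, seed = 3))
  j1 <- jackknife_snr(m, 1)
  s_ref <- matrix(apply(m$frames, 2, sd) / sqrt(200), m$shape[1])
  expect_lt(max(abs(j1$sigma - s_ref) / s_ref), 1e-8)
})

test_that("jackknife SNR scales with sqrt of the frame count", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(2, extent_nm = c(2400, 2400),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 2)
  m <- render_movie(ph, optics_camera(n_frames = 480, seed = 3))
  ja <- jackknife_snr(m, 2, frames = 1:240)
  jb <- jackknife_snr(m, 2)
  r <- median(jb$snr[is.finite(jb$snr)]) / median(ja$snr[is.finite(ja$snr)])
  expect_lt(abs(r - sqrt(2)) / sqrt(2), 0.15)

  const <- m
  const$frames <- matrix(5, 100, prod(m$shape))
  jc <- jackknife_snr(const, 2)
  expect_true(all(!is.finite(jc$snr)))
  expect_error(jackknife_snr(m, 2, frames = 1:20), "50")
})

test_that("jackknife agrees with a block bootstrap on the same movie", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(2, extent_nm = c(1600, 1600),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 12)
  m <- render_movie(ph, optics_camera(n_frames = 400, seed = 13))
  jk <- jackknife_snr(m, 2)
  set.seed(99)
  blocks <- split(1:400, rep(1:8, each = 50))
  boots <- vapply(1:50, function(b) {
    idx <- unlist(blocks[sample(8, 8, replace = TRUE)])
    xc <- sweep(m$frames[idx, ], 2, colMeans(m$frames[idx, ]))
    colMeans(xc^2)
  }, numeric(prod(m$shape)))
  sd_boot <- apply(boots, 1, sd)
  value <- as.vector(jk$value)
  snr_boot <- ifelse(sd_boot > 0, value / sd_boot, NA)
  med_jk <- median(jk$snr[is.finite(jk$snr)])
  med_bt <- median(snr_boot[is.finite(snr_boot)])
  expect_lt(abs(med_jk - med_bt) / med_bt, 0.30)
})

test_that("cross-section FWHM recovers an analytic Gaussian ridge", {
  sig_px <- 3
  img <- outer(1:64, 1:64, function(r, c)
    exp(-(r - 32.5)^2 / (2 * sig_px^2)))
  f <- cross_section_fwhm(img, p_start = c(10, 12), p_end = c(10, 52),
                          pixel_size_nm = 100)
  expect_lt(abs(f$fwhm_nm - 2 * sqrt(2 * log(2)) * sig_px * 100) /
              (2.355 * sig_px * 100), 0.02)
  # invariance to intensity scaling and offsets
  f2 <- cross_section_fwhm(5 * img + 40, c(10, 12), c(10, 52), 100)
  expect_equal(f2$fwhm_nm, f$fwhm_nm)
  expect_error(cross_section_fwhm(matrix(1, 20, 20), c(2, 2), c(2, 18), 100),
               "peak")
})

test_that("order-2 filament cross sections approach the PSF/sqrt(2) width", {
  kin <- dense_kinetics()
  straight <- data.frame(x_nm = seq(200, 3000, by = 20), y_nm = 1600)
  ph <- phantom(straight, c(3200, 3200), kin)
  m <- render_movie(ph, optics_camera(n_frames = 1500, psf_fwhm_nm = 320,
                                      seed = 41))
  ci <- flatten(cross_cumulant_image(m, 2))
  ps <- ci$pixel_size_nm
  f <- cross_section_fwhm(ci$values, p_start = c(1600 / ps, 800 / ps),
                          p_end = c(1600 / ps, 2400 / ps),
                          pixel_size_nm = ps)
  want <- 320 / sqrt(2)
  expect_lt(abs(f$fwhm_nm - want) / want, 0.10)
})

test_that("RSP/RSE scores are self-consistent and recover a known intensity
           map", {
  set.seed(6)
  sr <- paintsofi:::gauss_blur(matrix(rexp(96 * 96), 96), 1.5)
  ref <- 3 * paintsofi:::gauss_blur(sr, 4 / (2 * sqrt(2 * log(2)))) + 50
  sc <- rsp_rse(ref, sr, align = FALSE)
  expect_gt(sc$rsp, 0.999)
  expect_lt(sc$rse / sd(ref), 0.05)
  expect_lt(abs(sc$alpha - 3) / 3, 0.05)
  expect_lt(abs(sc$beta - 50), 5)

  # deleting structure lowers the RSP against a faithful reference
  sr_broken <- sr
  sr_broken[40:56, ] <- 0
  sc_broken <- rsp_rse(ref, sr_broken, align = FALSE)
  expect_lt(sc_broken$rsp, sc$rsp)
  expect_error(rsp_rse(matrix(1, 96, 96), sr), "reference")
})

test_that("std projection equals the square root of the order-2 cumulant", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(1, extent_nm = c(1600, 1600),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 7)
  m <- render_movie(ph, optics_camera(n_frames = 120, seed = 8))
  sp <- std_projection(m)
  # short movie on purpose: the identity is exact at any length
  k2 <- suppressWarnings(auto_cumulant_image(m, 2))$values
  expect_lt(max(abs(sp - sqrt(pmax(k2, 0)))), 1e-10)
  const <- m
  const$frames <- matrix(2, 10, prod(m$shape))
  expect_true(all(std_projection(const) == 0))
})
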