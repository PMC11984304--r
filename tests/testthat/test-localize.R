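# SMLM branch: detection, integrated-Gaussian fitting, uncertainty,
# drift correction, ASH rendering.

make_emitter_frame <- function(x0, y0, N = 5000, bg = 10, sigma = 1.3,
                               size = 21) {
  px <- diff(pnorm((0:size - x0) / sigma))
  py <- diff(pnorm((0:size - y0) / sigma))
  lam <- bg + N * outer(py, px)
  matrix(rpois(size * size, lam), size, size)
}

test_that("candidate detection behaves on noise, single and double
           emitters", {
  set.seed(11)
  noise <- matrix(rnorm(64 * 64, 100, 5), 64)
  cand <- detect_candidates(noise, threshold_factor = 3)
  expect_lt(nrow(cand), 0.001 * 64 * 64)

  set.seed(12)
  f1 <- make_emitter_frame(10.3, 9.7)
  c1 <- detect_candidates(f1, 3)
  expect_equal(nrow(c1), 1)
  expect_lt(abs(c1$col - 10.8), 1.1)
  expect_lt(abs(c1$row - 10.2), 1.1)

  f2 <- make_emitter_frame(6, 6) + make_emitter_frame(16, 16)
  c2 <- detect_candidates(f2, 3)
  expect_equal(nrow(c2), 2)
})

test_that("the integrated-Gaussian fit recovers noiseless positions to
           0.01 px", {
  x0 <- 10.30; y0 <- 7.75; sigma <- 1.3
  px <- diff(pnorm((0:21 - x0) / sigma))
  py <- diff(pnorm((0:21 - y0) / sigma))
  img <- 5 + 4000 * outer(py, px)
  rec <- fit_integrated_gaussian(img, list(row = 8, col = 10),
                                 fit_radius = 4, init_sigma = 1.6)
  expect_lt(abs(rec$x_px - x0), 0.01)
  expect_lt(abs(rec$y_px - y0), 0.01)
  expect_lt(abs(rec$sigma_px - sigma), 0.01)
  expect_lt(abs(rec$intensity - 4000) / 4000, 0.01)

  # init-independence on clean data
  rec2 <- fit_integrated_gaussian(img, list(row = 8, col = 10),
                                  fit_radius = 4, init_sigma = 3.2)
  expect_lt(abs(rec2$sigma_px - rec$sigma_px) / rec$sigma_px, 0.01)
  # border candidates are skipped
  expect_null(fit_integrated_gaussian(img, list(row = 2, col = 2), 4, 1.6))
})

test_that("localization scatter matches the precision formula within 25%", {
  set.seed(13)
  errs <- replicate(250, {
    f <- make_emitter_frame(10.3, 9.75, N = 5000, bg = 10)
    rec <- fit_integrated_gaussian(f, list(row = 10, col = 10), 4, 1.6)
    if (is.null(rec)) c(NA, NA) else c(rec$x_px - 10.3, rec$y_px - 9.75)
  })
  errs <- errs[, complete.cases(t(errs))]
  rmse_nm <- sqrt(mean(errs^2)) * 100
  pred_nm <- estimate_uncertainty(
    data.frame(sigma_px = 1.3, intensity = 5000, background = 10), 100)
  expect_lt(abs(rmse_nm - pred_nm) / pred_nm, 0.25)
})

test_that("uncertainty scales as 1/sqrt(N) and grows with background", {
  base <- data.frame(sigma_nm = 130, intensity = 5000, background = 10)
  quad <- transform(base, intensity = 20000)
  u1 <- estimate_uncertainty(base, 100)
  u4 <- estimate_uncertainty(quad, 100)
  expect_lt(abs(u4 / u1 - 0.5) / 0.5, 0.05)
  u_nobg <- estimate_uncertainty(transform(base, background = 0), 100)
  u_hibg <- estimate_uncertainty(transform(base, background = 50), 100)
  expect_lt(u_nobg, u_hibg)
  # single-digit nm for a typical bright event
  expect_lt(u1, 10)
  expect_gt(u1, 1)
  expect_error(estimate_uncertainty(transform(base, intensity = 0), 100),
               "intensity")
})

make_loc_table <- function(x, y, frame, n_frames) {
  t <- data.frame(frame = frame, x_nm = x, y_nm = y, sigma_nm = 130,
                  intensity = 5000, background = 10, uncertainty_nm = 5)
  attr(t, "n_frames") <- n_frames
  class(t) <- c("localization_table", "data.frame")
  t
}

test_that("drift correction recovers a linear drift and is quiet on null
           data", {
  set.seed(14)
  n <- 30000; nfr <- 5000
  frame <- sample(nfr, n, replace = TRUE)
  along <- runif(n, 400, 4400)
  f2 <- sample(2, n, replace = TRUE)
  x <- ifelse(f2 == 1, along, 1000) + rnorm(n, 0, 7)
  y <- ifelse(f2 == 1, 1805, along) + rnorm(n, 0, 7)

  drifted <- make_loc_table(x + 0.2 * frame, y, frame, nfr)
  fixed <- filter_and_drift_correct(drifted, 15)
  resid <- fixed$x_nm - x
  expect_lt(sqrt(mean((resid - mean(resid))^2)), 5)

  null_tab <- filter_and_drift_correct(make_loc_table(x, y, frame, nfr), 15)
  dr <- attr(null_tab, "drift")
  expect_lt(max(abs(c(dr$dx_nm, dr$dy_nm))), 2)

  # uncertainty filter removes everything above the threshold
  bad <- make_loc_table(x, y, frame, nfr)
  bad$uncertainty_nm <- 20
  expect_equal(nrow(suppressWarnings(filter_and_drift_correct(bad, 15))), 0)
})

test_that("ASH rendering conserves mass at any magnification", {
  set.seed(15)
  tab <- make_loc_table(runif(1e4, 0, 4000), runif(1e4, 0, 4000),
                        1, 1)
  attr(tab, "shape_px") <- c(40, 40)
  attr(tab, "pixel_size_nm") <- 100
  a5 <- render_ash(tab, 5)
  expect_equal(dim(a5), c(200, 200))
  expect_lt(abs(sum(a5) - 1e4) / 1e4, 0.001)
  a10 <- render_ash(tab, 10)
  expect_lt(abs(sum(a10) - 1e4) / 1e4, 0.001)

  single <- make_loc_table(1050, 950, 1, 1)
  attr(single, "shape_px") <- c(40, 40)
  attr(single, "pixel_size_nm") <- 100
  s <- render_ash(single, 5)
  expect_equal(sum(s), 1)
  pk <- which(s == max(s), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c(48, 53))  # bin of (y=950, x=1050) at 20 nm bins
})

test_that("end-to-end: bright sparse events localize within predicted
           uncertainty", {
  kin <- kinetic_params(per_site_binding_rate = 0.2, mean_bound_time = 0.3)
  sites <- data.frame(x_nm = c(800, 2400, 1600), y_nm = c(900, 1400, 2500))
  ph <- phantom(sites, c(3200, 3200), kin)
  opt <- optics_camera(frame_time_s = 0.1, n_frames = 300,
                       photons_per_bound_imager_per_s = 5e4,
                       background_photons_per_pixel_per_frame = 10,
                       seed = 44)
  m <- render_movie(ph, opt)
  tab <- localize_movie(m)
  tab <- tab[tab$intensity > 2000, ]
  expect_gt(nrow(tab), 10)
  d <- vapply(seq_len(nrow(tab)), function(i)
    min(sqrt((tab$x_nm[i] - sites$x_nm)^2 + (tab$y_nm[i] - sites$y_nm)^2)),
    numeric(1))
  frac <- mean(d <= 3 * tab$uncertainty_nm)
  expect_gt(frac, 0.9)
})
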