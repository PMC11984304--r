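# Blinking simulator: phantoms, binding traces, frame integration, movie
# rendering.

test_that("filament phantoms are reproducible and Poisson-decorated", {
  kin <- dense_kinetics()
  p1 <- make_filament_phantom(3, extent_nm = c(4000, 4000),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 5)
  p2 <- make_filament_phantom(3, extent_nm = c(4000, 4000),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 5)
  expect_identical(p1$sites, p2$sites)

  p0 <- make_filament_phantom(0, extent_nm = c(4000, 4000),
                              site_linear_density = 0.05, kinetics = kin)
  expect_equal(nrow(p0$sites), 0)

  # site count within 4 sd of the Poisson mean over the total arc length
  arc <- sum(vapply(p1$truth_geometry$filaments, function(cv)
    sum(sqrt(diff(cv[, 1])^2 + diff(cv[, 2])^2)), numeric(1)))
  lambda <- 0.05 * arc
  expect_lt(abs(nrow(p1$sites) - lambda), 4 * sqrt(lambda))

  expect_error(make_filament_phantom(1, extent_nm = c(100, 4000),
                                     site_linear_density = 0.05,
                                     kinetics = kin), "width")
})

test_that("point-pair phantoms place symmetric sites at the separation", {
  kin <- dense_kinetics()
  p <- make_point_pair_phantom(250, kin)
  d <- sqrt(diff(p$sites$x_nm)^2 + diff(p$sites$y_nm)^2)
  expect_equal(d, 250)
  expect_equal(mean(p$sites$x_nm), p$truth_geometry$center_nm[1])

  p0 <- make_point_pair_phantom(0, kin)
  expect_equal(p0$sites$x_nm[1], p0$sites$x_nm[2])
  expect_identical(p$kinetics, kin)
})

test_that("binding traces have exponential dwell statistics", {
  kin <- kinetic_params(per_site_binding_rate = 5, mean_bound_time = 0.04)
  tr <- simulate_binding_trace(kin, 4000, seed = 2)
  st <- binding_statistics(tr)
  expect_gt(st$n_events, 1e4)
  se_on <- sd(tr$t_unbind - tr$t_bind) / sqrt(st$n_events)
  expect_lt(abs(st$mean_on_s - 0.04), 3 * se_on)
  expect_lt(abs(st$mean_off_s - 0.2), 3 * 0.2 / sqrt(st$n_events))

  # no-binding limit
  tiny <- kinetic_params(per_site_binding_rate = 1e-12,
                         mean_bound_time = 0.04)
  expect_equal(nrow(simulate_binding_trace(tiny, 10, seed = 1)), 0)
  expect_error(simulate_binding_trace(kin, -1), "duration")
})

test_that("repeat motifs superpose linearly in event frequency", {
  rates <- vapply(c(1L, 2L, 5L), function(m) {
    k <- kinetic_params(per_site_binding_rate = 2, mean_bound_time = 0.05,
                        n_repeat_motifs = m)
    binding_statistics(simulate_binding_trace(k, 3000,
                                              seed = 10 + m))$events_per_s
  }, numeric(1))
  fit <- stats::lm(log(rates) ~ log(c(1, 2, 5)))
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  # 5x motif rate within 3 SE of 5x the single-motif rate
  n1 <- rates[1] * 3000
  expect_lt(abs(rates[3] / rates[1] - 5), 3 * 5 / sqrt(n1))
})

test_that("kinetics levers move the dwell times as configured", {
  base <- binding_statistics(simulate_binding_trace(
    kinetic_params(2, 0.05), 3000, seed = 30))
  faster <- binding_statistics(simulate_binding_trace(
    kinetic_params(4, 0.05), 3000, seed = 31))
  ec <- binding_statistics(simulate_binding_trace(
    kinetic_params(2, 0.05, destabilizer_on_time_factor = 0.5),
    3000, seed = 32))
  expect_lt(abs(faster$mean_off_s / base$mean_off_s - 0.5),
            3 * 0.5 / sqrt(base$n_events))
  expect_lt(abs(ec$mean_on_s / base$mean_on_s - 0.5),
            3 * 0.5 / sqrt(base$n_events))
})

test_that("occupancy integration is exact interval arithmetic", {
  tr <- data.frame(motif = 1L, t_bind = 0.02, t_unbind = 0.03)
  occ <- integrate_occupancy(tr, 0.01, 10)
  expect_equal(occ, c(0, 0, 0.01, rep(0, 7)))

  # boundary straddle at fraction f
  tr2 <- data.frame(motif = 1L, t_bind = 0.017, t_unbind = 0.023)
  occ2 <- integrate_occupancy(tr2, 0.01, 5)
  expect_equal(occ2[2], 0.003)
  expect_equal(occ2[3], 0.003)

  # conservation on random traces
  set.seed(8)
  kin <- dense_kinetics()
  for (i in 1:5) {
    tr3 <- simulate_binding_trace(kin, 10, seed = i)
    occ3 <- integrate_occupancy(tr3, 0.01, 1000)
    clipped <- sum(pmin(tr3$t_unbind, 10) - pmax(tr3$t_bind, 0))
    expect_lt(abs(sum(occ3) - clipped), 1e-9)
  }
  expect_error(integrate_occupancy(tr, 0, 10), "frame_time")
})

test_that("binding_statistics matches a hand-computed duty cycle", {
  tr <- structure(data.frame(motif = 1L, t_bind = 2, t_unbind = 3),
                  class = c("binding_trace", "data.frame"),
                  duration_s = 10)
  st <- binding_statistics(tr)
  expect_equal(st$duty_cycle, 0.1)
  expect_equal(st$mean_on_s, 1)
  empty <- structure(data.frame(motif = integer(0), t_bind = numeric(0),
                                t_unbind = numeric(0)),
                     class = c("binding_trace", "data.frame"),
                     duration_s = 10)
  st0 <- binding_statistics(empty)
  expect_true(st0$undefined)
  expect_equal(st0$n_events, 0)
})

test_that("rendered movies conserve photons with noise disabled", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(2, extent_nm = c(2000, 2000),
                              site_linear_density = 0.03, kinetics = kin,
                              seed = 3)
  opt <- optics_camera(n_frames = 50, camera_offset = 0, seed = 4)
  m <- render_movie(ph, opt, noise = FALSE, keep_traces = TRUE)
  traces <- attr(m, "traces")
  sig <- opt$psf_fwhm_nm / opt$pixel_size_nm / (2 * sqrt(2 * log(2)))
  H <- m$shape[1]; W <- m$shape[2]
  expected_sum <- rep(opt$background_photons_per_pixel_per_frame * H * W, 50)
  for (i in seq_len(nrow(ph$sites))) {
    occ <- integrate_occupancy(traces[[i]], opt$frame_time_s, 50)
    massx <- diff(stats::pnorm((c(0, W) - ph$sites$x_nm[i] / 100) / sig))
    massy <- diff(stats::pnorm((c(0, H) - ph$sites$y_nm[i] / 100) / sig))
    expected_sum <- expected_sum +
      occ * opt$photons_per_bound_imager_per_s * massx * massy
  }
  got <- rowSums(m$frames)
  expect_lt(max(abs(got - expected_sum) / expected_sum), 1e-6)
})

test_that("empty phantom renders offset plus background on average", {
  kin <- dense_kinetics()
  ph <- phantom(data.frame(x_nm = numeric(0), y_nm = numeric(0)),
                c(1600, 1600), kin)
  opt <- optics_camera(n_frames = 400,
                       background_photons_per_pixel_per_frame = 7,
                       camera_gain = 1, camera_offset = 100,
                       read_noise_sd = 0, seed = 6)
  m <- render_movie(ph, opt)
  mu <- mean(m$frames)
  se <- sd(m$frames) / sqrt(length(m$frames))
  expect_lt(abs(mu - 107), 3 * se + 0.5)  # 0.5 allows for count rounding
})

test_that("rendering is deterministic and drops outside sites with warning", {
  kin <- dense_kinetics()
  ph <- make_filament_phantom(1, extent_nm = c(1600, 1600),
                              site_linear_density = 0.05, kinetics = kin,
                              seed = 9)
  opt <- optics_camera(n_frames = 30, seed = 12)
  m1 <- render_movie(ph, opt)
  m2 <- render_movie(ph, opt)
  expect_identical(m1$frames, m2$frames)

  bad <- ph
  bad$sites <- rbind(bad$sites[, c("x_nm", "y_nm")],
                     data.frame(x_nm = 9999, y_nm = 10))
  bad$sites$site_id <- seq_len(nrow(bad$sites))
  expect_warning(render_movie(bad, opt), "outside")
})

test_that("adding a site does not perturb existing sites' traces", {
  kin <- dense_kinetics()
  sites <- data.frame(x_nm = c(400, 900), y_nm = c(500, 800))
  ph2 <- phantom(sites, c(1600, 1600), kin)
  ph3 <- phantom(rbind(sites, data.frame(x_nm = 1200, y_nm = 1200)),
                 c(1600, 1600), kin)
  opt <- optics_camera(n_frames = 40, seed = 13)
  t2 <- attr(render_movie(ph2, opt, keep_traces = TRUE), "traces")
  t3 <- attr(render_movie(ph3, opt, keep_traces = TRUE), "traces")
  expect_identical(t2[[1]]$t_bind, t3[[1]]$t_bind)
  expect_identical(t2[[2]]$t_bind, t3[[2]]$t_bind)
})
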