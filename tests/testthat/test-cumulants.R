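# Joint cumulants, auto/cross cumulant images, subsequences, combination.

test_that("joint_cumulant matches the brute-force partition oracle", {
  set.seed(42)
  for (n in 2:6) {
    for (rep in 1:3) {
      x <- matrix(rnorm(n * 40, mean = 2), ncol = n)
      got <- joint_cumulant(x)
      want <- oracle_joint_cumulant(x)
      expect_lt(abs(got - want) / max(abs(want), 1e-12), 1e-10)
    }
  }
})

test_that("joint_cumulant has the covariance, constancy and symmetry
           properties", {
  set.seed(1)
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(joint_cumulant(cbind(a, b)),
               mean(a * b) - mean(a) * mean(b))
  # constants have vanishing cumulants beyond order 1
  expect_equal(joint_cumulant(cbind(a, rep(3, 300), b)), 0)
  # permutation symmetry
  c3 <- rnorm(300)
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  vals <- vapply(perms, function(p)
    joint_cumulant(cbind(a, b, c3)[, p]), numeric(1))
  expect_lt(diff(range(vals)) / max(abs(vals)), 1e-12)
  expect_error(joint_cumulant(list(a, rnorm(10))), "length")
})

test_that("Bernoulli occupancy reproduces closed-form cumulants", {
  set.seed(7)
  rho <- 0.25
  x <- rbinom(4e5, 1, rho)
  k2 <- rho * (1 - rho)
  k3 <- rho * (1 - rho) * (1 - 2 * rho)
  k4 <- rho * (1 - rho) * (1 - 6 * rho + 6 * rho^2)
  expect_lt(abs(joint_cumulant(x, 2) - k2), 3 * chunked_se(x, 2))
  expect_lt(abs(joint_cumulant(x, 3) - k3), 3 * chunked_se(x, 3))
  expect_lt(abs(joint_cumulant(x, 4) - k4), 3 * chunked_se(x, 4))
})

test_that("auto-cumulant images obey the PSF power law", {
  m <- single_emitter_movie(n_frames = 1500)
  psf_px <- 320 / 100
  for (n in c(2L, 3L)) {
    ci <- auto_cumulant_image(m, n)
    expect_equal(ci$oversampling, 1L)
    expect_true(all(ci$distance_factors == 1))
    fit <- paintsofi:::fit_gaussian_peak(abs(ci$values))
    expect_lt(abs(fit$fwhm_px - psf_px / sqrt(n)) / (psf_px / sqrt(n)), 0.05)
  }
  expect_error(auto_cumulant_image(m, 7), "order")
})

test_that("cumulant images of independent sources are additive", {
  m1 <- single_emitter_movie(n_frames = 1200, seed = 21,
                             extent_nm = c(2100, 2100))
  kin <- kinetic_params(per_site_binding_rate = 2, mean_bound_time = 0.05)
  ph2 <- phantom(data.frame(x_nm = 500, y_nm = 500), c(2100, 2100), kin)
  opt <- optics_camera(n_frames = 1200,
                       background_photons_per_pixel_per_frame = 0.01,
                       read_noise_sd = 0, camera_offset = 0, seed = 99)
  m2 <- render_movie(ph2, opt, noise = FALSE)
  msum <- m1
  msum$frames <- m1$frames + m2$frames
  for (n in c(2L, 3L)) {
    k_sum <- auto_cumulant_image(msum, n)$values
    k_ind <- auto_cumulant_image(m1, n)$values +
      auto_cumulant_image(m2, n)$values
    scale <- max(abs(k_ind))
    expect_lt(max(abs(k_sum - k_ind)) / scale, 0.02)
  }
})

test_that("cross-cumulant lattices agree with auto values and direct joint
           cumulants", {
  m <- single_emitter_movie(n_frames = 800)
  x2 <- cross_cumulant_image(m, 2)
  a2 <- auto_cumulant_image(m, 2)
  ii <- seq(1, nrow(x2$values), by = 2)
  expect_lt(max(abs(x2$values[ii, ii] - a2$values) / max(abs(a2$values))),
            1e-10)
  # half-integer lattice point equals the joint cumulant of the two pixels
  H <- m$shape[1]
  s_a <- m$frames[, 10 * H + 11]
  s_b <- m$frames[, 11 * H + 11]
  expect_equal(x2$values[21, 22], joint_cumulant(cbind(s_a, s_b)))
  # symmetry of the combination: the value does not depend on slot order
  expect_equal(joint_cumulant(cbind(s_a, s_b)),
               joint_cumulant(cbind(s_b, s_a)), tolerance = 1e-12)
})

test_that("flattened single-emitter cross-cumulant surface has no lattice
           parity gain", {
  m <- single_emitter_movie(n_frames = 1200)
  x2 <- cross_cumulant_image(m, 2)
  fl <- x2$values / x2$distance_factors
  fit <- paintsofi:::fit_gaussian_peak(paintsofi:::fill_edge_na(fl))
  H <- nrow(fl); W <- ncol(fl)
  model <- outer(seq_len(H), seq_len(W), function(r, c)
    fit$A * exp(-((c - fit$x0)^2 + (r - fit$y0)^2) / (2 * fit$s^2)) + fit$c0)
  core <- abs(model - fit$c0) > 0.05 * fit$A & !is.na(fl)
  ratio <- (fl - fit$c0)[core] / (model - fit$c0)[core]
  par_r <- (row(fl)[core] - 1) %% 2
  par_c <- (col(fl)[core] - 1) %% 2
  cls <- paste(par_r, par_c)
  means <- tapply(ratio, cls, mean)
  expect_lt(max(means) / min(means) - 1, 0.05)
})

test_that("subsequence splitting follows the block rules", {
  p5000 <- split_subsequences(5000)
  expect_length(p5000$blocks, 5)
  expect_true(all(lengths(p5000$blocks) == 1000))
  expect_equal(p5000$dropped, 0)

  p500 <- split_subsequences(500)
  expect_length(p500$blocks, 1)
  expect_length(p500$blocks[[1]], 500)

  p2500 <- split_subsequences(2500)
  expect_length(p2500$blocks, 2)
  expect_equal(p2500$dropped, 500)
})

test_that("subsequence combination registers known shifts and averages", {
  m <- single_emitter_movie(n_frames = 600)
  ci <- cross_cumulant_image(m, 2)
  same <- combine_subsequence_cumulants(list(ci, ci))
  expect_equal(same$values, ci$values)
  expect_equal(same$provenance$shifts[[2]], c(0, 0), tolerance = 1e-6)

  shifted <- ci
  shifted$values <- paintsofi:::shift_int(
    paintsofi:::fill_edge_na(ci$values), 3, -2)
  shifted$values[is.na(shifted$values)] <- 0
  comb <- combine_subsequence_cumulants(list(ci, shifted))
  sh <- comb$provenance$shifts[[2]]   # block 2 displaced down 3, left 2
  expect_lt(abs(sh[1] - 3), 0.2)
  expect_lt(abs(sh[2] - (-2)), 0.2)

  one <- combine_subsequence_cumulants(list(ci))
  expect_identical(one$values, ci$values)
})
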