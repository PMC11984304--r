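## Quantitative QC: decorrelation resolution, jackknife SNR maps,
## cross-section FWHM and resolution-scaled error / Pearson scores.

#' Image resolution by decorrelation analysis
#'
#' Cross-correlates the image spectrum with its phase-normalized version
#' under binary circular Fourier masks of diminishing radius (partial phase
#' autocorrelation). The decorrelation curve d(r) is evaluated at `n_radii`
#' equidistant normalized frequencies in (0, 1], for the raw image and for
#' `n_filters` progressively stronger Gaussian high-pass filtered versions.
#' The cutoff is the highest significant local-maximum radius across all
#' curves (peak prominence above the curve tail > 0.05, a stated default),
#' and resolution = 2 * pixel size / cutoff. Image borders are apodized with
#' a cosine ramp before the FFT.
#'
#' @param image numeric matrix, at least 64 x 64, finite.
#' @param pixel_size_nm pixel pitch of `image` in nm (lattice pixels for
#'   oversampled SOFI images).
#' @param n_radii number of mask radii (default 100).
#' @param n_filters number of high-pass filters (default 20).
#' @return object of class `resolution_estimate`: list with `resolution_nm`,
#'   `cutoff` (normalized frequency), and per-curve peak diagnostics.
#' @export
decorrelation_resolution <- function(image, pixel_size_nm,
                                     n_radii = 100L, n_filters = 20L) {
  if (nrow(image) < 64 || ncol(image) < 64)
    stop("image must be at least 64 x 64")
  if (!all(is.finite(image))) stop("image must be finite")
  if (sd(image) == 0) stop("no spectral content: image is flat")
  img <- apodize_edges(image - mean(image))
  Fk <- fft(img)
  H <- nrow(img); W <- ncol(img)
  fy <- ((seq_len(H) - 1 + H %/% 2) %% H - H %/% 2) / (H / 2)
  fx <- ((seq_len(W) - 1 + W %/% 2) %% W - W %/% 2) / (W / 2)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  keep <- rad <= 1 & rad > 0           # unit disk, DC excluded
  r_pix <- rad[keep]
  amp <- Mod(Fk)[keep]
  ord <- order(r_pix)
  r_sorted <- r_pix[ord]
  amp_sorted <- amp[ord]
  radii <- seq(0, 1, length.out = n_radii)[-1]
  n_below <- findInterval(radii, r_sorted)
  widths <- 10^seq(log10(0.05), 0, length.out = n_filters)
  curves <- matrix(NA_real_, nrow = length(radii), ncol = n_filters + 1L)
  peak_r <- rep(NA_real_, n_filters + 1L)
  peak_a <- rep(NA_real_, n_filters + 1L)
  for (i in 0:n_filters) {
    hp <- if (i == 0) rep(1, length(r_sorted)) else
      1 - exp(-r_sorted^2 / (2 * widths[i]^2))
    a <- amp_sorted * hp
    num <- cumsum(a)[pmax(n_below, 1)]
    num[n_below == 0] <- 0
    den <- sqrt(sum(a^2) * pmax(n_below, 1))
    d <- ifelse(n_below > 0, num / den, 0)
    curves[, i + 1L] <- d
    pk <- find_significant_peak(radii, d)
    peak_r[i + 1L] <- pk[1]; peak_a[i + 1L] <- pk[2]
  }
  cutoff <- suppressWarnings(max(peak_r, na.rm = TRUE))
  if (!is.finite(cutoff)) {
    # fall back to the raw-curve global maximum
    cutoff <- radii[which.max(curves[, 1])]
  }
  structure(list(resolution_nm = 2 * pixel_size_nm / cutoff,
                 cutoff = cutoff, radii = radii, curves = curves,
                 peak_radii = peak_r, peak_amplitudes = peak_a,
                 pixel_size_nm = pixel_size_nm),
            class = "resolution_estimate")
}

# Highest-frequency interior local maximum whose prominence over the
# following tail minimum exceeds 0.05 (stated default). Curves that only
# rise monotonically (e.g. pure white noise) yield no peak here; the caller
# falls back to the global maximum of the unfiltered curve, which then sits
# at the highest radius.
find_significant_peak <- function(radii, d, prominence = 0.05) {
  n <- length(d)
  best_r <- NA_real_; best_a <- NA_real_
  for (i in seq(2, n - 1)) {
    if (!(d[i] >= d[i - 1] && d[i] > d[i + 1])) next
    if ((d[i] - min(d[i:n])) > prominence && radii[i] > (best_r %|NA|% -Inf)) {
      best_r <- radii[i]; best_a <- d[i]
    }
  }
  c(best_r, best_a)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf("<resolution_estimate> %.1f nm (cutoff %.3f, %.2f nm/px)\n",
              x$resolution_nm, x$cutoff, x$pixel_size_nm))
  invisible(x)
}

# Cosine ramp of 10% of each dimension on every border.
apodize_edges <- function(img, fraction = 0.1) {
  ramp <- function(n) {
    L <- max(2L, round(fraction * n))
    w <- rep(1, n)
    edge <- 0.5 * (1 - cos(pi * (seq_len(L) - 0.5) / L))
    w[seq_len(L)] <- edge
    w[n + 1 - seq_len(L)] <- edge
    w
  }
  img * outer(ramp(nrow(img)), ramp(ncol(img)))
}

#' Per-pixel SNR by leave-one-frame-out jackknife
#'
#' The N leave-one-frame-out auto-cumulant images I_n(x, y) are produced
#' from updatable power-sum accumulators (no recomputation per frame), the
#' per-pixel uncertainty is the jackknife standard error
#' `sigma = sqrt(((N - 1) / N) * sum_n (I_n - mean(I_n))^2)` and
#' `SNR = I / sigma`, non-finite where `sigma = 0` (e.g. a constant movie).
#' Order 1 (the mean image) reproduces the closed-form standard error of the
#' mean, `s / sqrt(N)`, exactly.
#'
#' @param movie a [movie_stack].
#' @param order cumulant order in 1..4.
#' @param frames optional frame subset (at least 50 frames).
#' @return object of class `snr_map`: list with `snr`, `sigma`, `value`
#'   matrices and `n`.
#' @export
jackknife_snr <- function(movie, order = 2L, frames = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!(order %in% 1:4)) stop("order must be in 1..4")
  X <- movie$frames
  if (!is.null(frames)) X <- X[frames, , drop = FALSE]
  N <- nrow(X)
  if (N < 50) stop("at least 50 frames are required")
  jk <- cpp_jackknife_moments(X, as.integer(order))
  sigma2 <- (N - 1) / N * (jk$sumsq - jk$sum^2 / N)
  sigma <- sqrt(pmax(sigma2, 0))
  value <- if (order == 1) colMeans(X) else {
    xc <- sweep(X, 2L, colMeans(X))
    auto_cumulant_from_central(xc, order)
  }
  snr <- ifelse(sigma > 0, value / sigma, NaN)
  shp <- movie$shape
  structure(list(snr = matrix(snr, shp[1], shp[2]),
                 sigma = matrix(sigma, shp[1], shp[2]),
                 value = matrix(value, shp[1], shp[2]), n = N,
                 order = order),
            class = "snr_map")
}

#' FWHM of a structure cross-section
#'
#' Samples the image along the segment from `p_start` to `p_end` (continuous
#' pixel coordinates `c(x, y)`, origin at the image corner) by bilinear
#' interpolation at <= 0.25 px spacing, subtracts the baseline (mean of the
#' outer 20% of the profile), normalizes the peak to 1 and measures the full
#' width at half maximum by linear interpolation of the half-max crossings.
#'
#' @param image numeric matrix.
#' @param p_start,p_end line endpoints, `c(x, y)` in pixel units.
#' @param pixel_size_nm pixel pitch of `image` in nm (use the lattice pitch
#'   for oversampled SOFI images).
#' @return object of class `fwhm_measurement`: list with `fwhm_nm`,
#'   `profile`, `positions_nm`, `crossings_nm`.
#' @export
cross_section_fwhm <- function(image, p_start, p_end, pixel_size_nm) {
  len_px <- sqrt(sum((p_end - p_start)^2))
  if (len_px <= 0) stop("degenerate line")
  n_s <- max(8L, ceiling(len_px / 0.25) + 1L)
  tfrac <- seq(0, 1, length.out = n_s)
  xs <- p_start[1] + tfrac * (p_end[1] - p_start[1])
  ys <- p_start[2] + tfrac * (p_end[2] - p_start[2])
  prof <- bilinear_sample(image, ys + 0.5, xs + 0.5)
  n_edge <- max(1L, round(0.1 * n_s))
  baseline <- mean(c(prof[seq_len(n_edge)], prof[n_s + 1 - seq_len(n_edge)]))
  prof0 <- prof - baseline
  pk <- which.max(prof0)
  if (prof0[pk] <= 0) stop("no peak above the baseline")
  prof_n <- prof0 / prof0[pk]
  cross_at <- function(idx_range, rising) {
    for (i in idx_range) {
      a <- prof_n[i]; b <- prof_n[i + 1]
      if ((rising && a < 0.5 && b >= 0.5) || (!rising && a >= 0.5 && b < 0.5))
        return(i + (0.5 - a) / (b - a))
    }
    NA_real_
  }
  left <- cross_at(seq(pk - 1, 1), rising = TRUE)
  right <- cross_at(seq(pk, n_s - 1), rising = FALSE)
  if (is.na(left) || is.na(right))
    stop("half-maximum crossings do not bracket the peak")
  spacing_nm <- len_px * pixel_size_nm / (n_s - 1)
  structure(list(fwhm_nm = (right - left) * spacing_nm,
                 profile = prof_n,
                 positions_nm = tfrac * len_px * pixel_size_nm,
                 crossings_nm = c(left, right) * spacing_nm,
                 baseline = baseline),
            class = "fwhm_measurement")
}

#' Resolution-scaled Pearson correlation and error
#'
#' Registers the super-resolution image to the reference (temporal
#' standard-deviation projection of the raw movie in the intended use),
#' optimizes the Gaussian resolution scaling function width and the linear
#' intensity mapping `alpha * blur(SR) + beta` to minimize the RMSE against
#' the reference, and reports the minimized RSE and the Pearson RSP at the
#' optimum.
#'
#' @param reference reference image matrix (camera grid).
#' @param sr super-resolution image; if its dimensions are an integer
#'   multiple of the reference it is block-averaged onto the reference grid.
#' @param fwhm_range search bounds for the RSF FWHM in reference pixels.
#' @param align estimate and apply an integer + sub-pixel shift first.
#' @return object of class `artifact_scores`: list with `rsp`, `rse`,
#'   `alpha`, `beta`, `rsf_fwhm_px`.
#' @export
rsp_rse <- function(reference, sr, fwhm_range = c(0.5, 20), align = TRUE) {
  if (sd(reference) == 0) stop("degenerate (constant) reference image")
  fac <- nrow(sr) / nrow(reference)
  if (fac > 1) {
    if (fac != round(fac) || ncol(sr) / ncol(reference) != fac)
      stop("sr dimensions must be an integer multiple of the reference")
    sr <- block_average(sr, fac)
  }
  stopifnot(all(dim(sr) == dim(reference)))
  if (align) {
    sh <- estimate_shift(reference, sr, max_shift = 5L)
    sr <- shift_image(sr, sh[1], sh[2])
  }
  fit_at <- function(fwhm) {
    B <- gauss_blur(sr, fwhm / (2 * sqrt(2 * log(2))))
    vb <- stats::var(as.vector(B))
    alpha <- if (vb > 0)
      stats::cov(as.vector(reference), as.vector(B)) / vb else 0
    beta <- mean(reference) - alpha * mean(B)
    resid <- reference - (alpha * B + beta)
    list(rmse = sqrt(mean(resid^2)), alpha = alpha, beta = beta, B = B)
  }
  opt <- optimize(function(f) fit_at(f)$rmse, interval = fwhm_range)
  best <- fit_at(opt$minimum)
  structure(list(rsp = stats::cor(as.vector(reference),
                                  as.vector(best$alpha * best$B + best$beta)),
                 rse = best$rmse, alpha = best$alpha, beta = best$beta,
                 rsf_fwhm_px = opt$minimum),
            class = "artifact_scores")
}

#' Temporal standard-deviation projection
#'
#' Per-pixel standard deviation over frames with 1/T normalization; equals
#' the square root of the order-2 auto-cumulant image. Used as the
#' diffraction-limited reference for [rsp_rse()].
#'
#' @param movie a [movie_stack] with at least 2 frames.
#' @return rows x cols matrix.
#' @export
std_projection <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  X <- movie$frames
  if (nrow(X) < 2) stop("at least 2 frames required")
  v <- colMeans(X^2) - colMeans(X)^2
  matrix(sqrt(pmax(v, 0)), movie$shape[1], movie$shape[2])
}
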