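## Minimal single-molecule localization branch: DoG detection,
## pixel-integrated Gaussian fitting by weighted least squares, Thompson
## uncertainty, uncertainty filtering + drift correction, ASH rendering.
##
## Conventions: continuous positions are in pixel units with the origin at
## the field corner (pixel (0,0) covers [0,1)^2), converted to nm with the
## camera pixel size in the localization table.

#' Detect localization candidates in one frame
#'
#' Difference-of-Gaussians band-pass (equivalent defaults to the common
#' wavelet filter cascade), followed by 8-connected local maxima above
#' `threshold_factor` times the robust noise SD (1.4826 x MAD) of the
#' filtered frame, deduplicated within 2 px (brightest wins).
#'
#' @param frame_image numeric matrix (single frame, photon or count units).
#' @param threshold_factor detection threshold in robust noise SDs.
#' @param dog_sigmas the two Gaussian widths (px) of the band-pass.
#' @return data.frame with integer `row`, `col` (1-based) and filter `value`;
#'   zero rows when nothing is detected.
#' @export
detect_candidates <- function(frame_image, threshold_factor = 3,
                              dog_sigmas = c(1, 2)) {
  f <- gauss_blur(frame_image, dog_sigmas[1]) -
    gauss_blur(frame_image, dog_sigmas[2])
  noise_sd <- mad(as.vector(f))
  if (noise_sd == 0) noise_sd <- sd(as.vector(f))
  if (noise_sd == 0) return(data.frame(row = integer(0), col = integer(0),
                                       value = numeric(0)))
  thr <- threshold_factor * noise_sd
  H <- nrow(f); W <- ncol(f)
  is_max <- f > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- f[pmin(pmax(seq_len(H) + dr, 1L), H),
            pmin(pmax(seq_len(W) + dc, 1L), W), drop = FALSE]
    is_max <- is_max & (f >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(data.frame(row = integer(0), col = integer(0),
                                        value = numeric(0)))
  cand <- data.frame(row = idx[, 1], col = idx[, 2], value = f[idx])
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    close <- keep & abs(cand$row - cand$row[i]) <= 2 &
      abs(cand$col - cand$col[i]) <= 2
    close[i] <- FALSE
    keep[close] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a pixel-integrated Gaussian to one candidate
#'
#' Weighted least squares (weights `1 / max(counts, 1)`) of the model
#' `b + N * [Phi((c - x)/s) - Phi((c - 1 - x)/s)] * [same in y]` on a square
#' window of half-width `fit_radius` px. Candidates closer than `fit_radius`
#' to the border are skipped; non-converging or singular fits are dropped.
#'
#' @param frame_image numeric matrix in photon units.
#' @param candidate list or one-row data.frame with `row`, `col`.
#' @param fit_radius window half-width in px.
#' @param init_sigma starting PSF sigma in px.
#' @return one-row data.frame with `x_px`, `y_px`, `sigma_px`, `intensity`
#'   (photons), `background` (photons/px), or NULL when skipped/dropped.
#' @export
fit_integrated_gaussian <- function(frame_image, candidate, fit_radius = 4L,
                                    init_sigma = 1.6) {
  r <- candidate$row[1]; c <- candidate$col[1]
  H <- nrow(frame_image); W <- ncol(frame_image)
  if (r <= fit_radius || r > H - fit_radius ||
      c <= fit_radius || c > W - fit_radius)
    return(NULL)
  rows <- (r - fit_radius):(r + fit_radius)
  cols <- (c - fit_radius):(c + fit_radius)
  z <- as.vector(frame_image[rows, cols])
  d <- data.frame(z = z,
                  py = rep(rows, times = length(cols)),
                  px = rep(cols, each = length(rows)))
  border <- d$py %in% range(rows) | d$px %in% range(cols)
  b0 <- median(d$z[border])
  start <- list(x0 = c - 0.5, y0 = r - 0.5, s = init_sigma,
                N = max(sum(d$z - b0), 10), b = b0)
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      z ~ b + N *
        (pnorm((px - x0) / s) - pnorm((px - 1 - x0) / s)) *
        (pnorm((py - y0) / s) - pnorm((py - 1 - y0) / s)),
      data = d, start = start, weights = 1 / pmax(d$z, 1),
      control = minpack.lm::nls.lm.control(maxiter = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) return(NULL)
  p <- as.list(coef(fit))
  if (!all(is.finite(unlist(p))) || p$N <= 0 || abs(p$s) > 4 * init_sigma ||
      abs(p$x0 - (c - 0.5)) > fit_radius || abs(p$y0 - (r - 0.5)) > fit_radius)
    return(NULL)
  data.frame(x_px = p$x0, y_px = p$y0, sigma_px = abs(p$s),
             intensity = p$N, background = p$b)
}

#' Thompson-style lateral localization uncertainty
#'
#' `sigma_loc^2 = (s^2 + a^2/12) / N + 8 pi s^4 b^2 / (a^2 N^2)` with `s`
#' the fitted PSF sigma (nm), `a` the pixel size (nm), `N` the photon count
#' and `b` the background noise SD in photons per pixel (the square root of
#' the fitted Poisson background level is used by [localize_movie()]).
#' Decreasing in N; quadrupling the photons halves the uncertainty.
#'
#' @param records data.frame with `sigma_px` (or `sigma_nm`), `intensity`,
#'   `background` columns.
#' @param pixel_size_nm camera pixel size.
#' @return numeric vector of uncertainties in nm.
#' @export
estimate_uncertainty <- function(records, pixel_size_nm) {
  if (any(records$intensity <= 0)) stop("intensity must be > 0")
  s <- if (!is.null(records$sigma_nm)) records$sigma_nm
       else records$sigma_px * pixel_size_nm
  a <- pixel_size_nm
  N <- records$intensity
  b <- sqrt(pmax(records$background, 0))
  sqrt((s^2 + a^2 / 12) / N + 8 * pi * s^4 * b^2 / (a^2 * N^2))
}

#' Localize all frames of a movie
#'
#' Converts counts to photons with the camera gain/offset from the metadata,
#' detects candidates per frame, fits the pixel-integrated Gaussian and
#' attaches Thompson uncertainties.
#'
#' @param movie a [movie_stack].
#' @param threshold_factor detection threshold (robust noise SDs).
#' @param fit_radius fitting window half-width (px).
#' @param init_sigma initial PSF sigma (px).
#' @return a `localization_table`: data.frame with `frame`, `x_nm`, `y_nm`,
#'   `sigma_nm`, `intensity`, `background`, `uncertainty_nm`, sorted by
#'   frame; pixel size, field shape and counts of dropped fits as
#'   attributes.
#' @export
localize_movie <- function(movie, threshold_factor = 3, fit_radius = 4L,
                           init_sigma = 1.6) {
  stopifnot(inherits(movie, "movie_stack"))
  ps <- movie$meta$pixel_size_nm
  gain <- movie$meta$camera_gain %||% 1
  offset <- movie$meta$camera_offset %||% 0
  rows_out <- list()
  dropped <- 0L
  for (t in seq_len(nrow(movie$frames))) {
    img <- (movie_frame(movie, t) - offset) / gain
    cand <- detect_candidates(img, threshold_factor)
    for (i in seq_len(nrow(cand))) {
      rec <- fit_integrated_gaussian(img, cand[i, ], fit_radius, init_sigma)
      if (is.null(rec)) { dropped <- dropped + 1L; next }
      rec$frame <- t
      rows_out[[length(rows_out) + 1L]] <- rec
    }
  }
  tab <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(x_px = numeric(0), y_px = numeric(0), sigma_px = numeric(0),
               intensity = numeric(0), background = numeric(0),
               frame = integer(0))
  out <- data.frame(frame = tab$frame,
                    x_nm = tab$x_px * ps, y_nm = tab$y_px * ps,
                    sigma_nm = tab$sigma_px * ps,
                    intensity = tab$intensity, background = tab$background)
  out$uncertainty_nm <- if (nrow(out)) estimate_uncertainty(
    data.frame(sigma_nm = out$sigma_nm, intensity = out$intensity,
               background = out$background), ps) else numeric(0)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("localization_table", "data.frame"),
            pixel_size_nm = ps, shape_px = movie$shape,
            n_frames = nrow(movie$frames), dropped_fits = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uncertainty filtering and cross-correlation drift correction
#'
#' Localizations with uncertainty above `max_uncertainty_nm` are removed
#' first. The remaining table is split into temporal blocks of `bin_frames`
#' frames, each block is rendered as a 2-D histogram, block shifts relative
#' to the first block are estimated by cross-correlation with sub-pixel
#' refinement, linearly interpolated per frame and subtracted. With fewer
#' than 2 blocks only the filter is applied (with a warning).
#'
#' @param table a `localization_table`.
#' @param max_uncertainty_nm uncertainty threshold (nm, ThunderSTORM
#'   convention).
#' @param bin_frames frames per drift block (default: one twentieth of the
#'   acquisition).
#' @param hist_bin_nm histogram bin size for drift estimation.
#' @return the corrected `localization_table`; estimated per-block drift is
#'   attached as attribute `"drift"`.
#' @export
filter_and_drift_correct <- function(table, max_uncertainty_nm = 15,
                                     bin_frames = NULL, hist_bin_nm = 25) {
  stopifnot(nrow(table) >= 1)
  atts <- attributes(table)
  tab <- table[table$uncertainty_nm <= max_uncertainty_nm, , drop = FALSE]
  if (nrow(tab) == 0) {
    out <- tab
  } else {
    n_frames <- atts$n_frames %||% max(tab$frame)
    if (is.null(bin_frames)) bin_frames <- max(1L, ceiling(n_frames / 20))
    n_blocks <- ceiling(n_frames / bin_frames)
    if (n_blocks < 2) {
      warning("fewer than 2 drift blocks: uncertainty filter only")
      out <- tab
    } else {
      extent <- c(max(tab$x_nm), max(tab$y_nm)) * 1.02 + hist_bin_nm
      render_block <- function(sub) {
        nx <- ceiling(extent[1] / hist_bin_nm)
        ny <- ceiling(extent[2] / hist_bin_nm)
        ix <- pmin(pmax(floor(sub$x_nm / hist_bin_nm) + 1L, 1L), nx)
        iy <- pmin(pmax(floor(sub$y_nm / hist_bin_nm) + 1L, 1L), ny)
        m <- matrix(0, ny, nx)
        for (k in seq_along(ix)) m[iy[k], ix[k]] <- m[iy[k], ix[k]] + 1
        m
      }
      blk <- pmin((tab$frame - 1L) %/% bin_frames + 1L, n_blocks)
      ref <- render_block(tab[blk == 1L, , drop = FALSE])
      centers <- (seq_len(n_blocks) - 0.5) * bin_frames
      drift <- matrix(0, n_blocks, 2)
      max_shift <- max(20L, ceiling(min(dim(ref)) / 3))
      for (b in seq_len(n_blocks)[-1]) {
        sub <- tab[blk == b, , drop = FALSE]
        if (nrow(sub) < 5) { drift[b, ] <- drift[b - 1, ]; next }
        sh <- estimate_shift(ref, render_block(sub), max_shift = max_shift)
        drift[b, ] <- c(sh[2], sh[1]) * hist_bin_nm   # (dx, dy) nm
      }
      interp_extrap <- function(vals) {
        f <- approx(centers, vals, xout = tab$frame, rule = 2)$y
        nb <- length(centers)
        lo <- tab$frame < centers[1]
        hi <- tab$frame > centers[nb]
        slope_lo <- (vals[2] - vals[1]) / (centers[2] - centers[1])
        slope_hi <- (vals[nb] - vals[nb - 1]) / (centers[nb] - centers[nb - 1])
        f[lo] <- vals[1] + slope_lo * (tab$frame[lo] - centers[1])
        f[hi] <- vals[nb] + slope_hi * (tab$frame[hi] - centers[nb])
        f
      }
      fx <- interp_extrap(drift[, 1])
      fy <- interp_extrap(drift[, 2])
      tab$x_nm <- tab$x_nm - fx
      tab$y_nm <- tab$y_nm - fy
      out <- tab
      attr(out, "drift") <- data.frame(block = seq_len(n_blocks),
                                       center_frame = centers,
                                       dx_nm = drift[, 1], dy_nm = drift[, 2])
    }
  }
  for (nm in setdiff(names(atts), c("row.names", "names")))
    attr(out, nm) <- atts[[nm]]
  rownames(out) <- NULL
  out
}

#' Averaged-shifted-histogram rendering
#'
#' Renders a localization table on a grid `magnification` times finer than
#' the camera pixels using 2x2 averaged shifted histograms (triangular
#' kernel); edge contributions are folded back so the total mass equals the
#' record count exactly.
#'
#' @param table a `localization_table`.
#' @param magnification lattice refinement relative to camera pixels.
#' @param shape_px camera field c(rows, cols); defaults to the table
#'   attribute.
#' @param pixel_size_nm camera pixel size; defaults to the table attribute.
#' @return rendered image matrix (rows * magnification x cols *
#'   magnification) with attribute `pixel_size_nm` of the fine grid.
#' @export
render_ash <- function(table, magnification = 5.0, shape_px = NULL,
                       pixel_size_nm = NULL) {
  stopifnot(nrow(table) >= 1)
  shape_px <- shape_px %||% attr(table, "shape_px")
  pixel_size_nm <- pixel_size_nm %||% attr(table, "pixel_size_nm")
  if (is.null(shape_px) || is.null(pixel_size_nm))
    stop("shape_px and pixel_size_nm are required (or table attributes)")
  bin_nm <- pixel_size_nm / magnification
  ny <- round(shape_px[1] * magnification)
  nx <- round(shape_px[2] * magnification)
  ix <- pmin(pmax(floor(table$x_nm / bin_nm) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(table$y_nm / bin_nm) + 1L, 1L), ny)
  hist <- matrix(0, ny + 2L, nx + 2L)
  for (k in seq_along(ix))
    hist[iy[k] + 1L, ix[k] + 1L] <- hist[iy[k] + 1L, ix[k] + 1L] + 1
  k1 <- c(0.25, 0.5, 0.25)
  smooth_axis <- function(m) {
    up <- rbind(m[-1, , drop = FALSE], 0)
    dn <- rbind(0, m[-nrow(m), , drop = FALSE])
    k1[2] * m + k1[1] * up + k1[3] * dn
  }
  sm <- t(smooth_axis(t(smooth_axis(hist))))
  # fold padded margins back to conserve mass
  sm[2, ] <- sm[2, ] + sm[1, ]; sm[ny + 1L, ] <- sm[ny + 1L, ] + sm[ny + 2L, ]
  core <- sm[2:(ny + 1L), , drop = FALSE]
  core[, 2] <- core[, 2] + core[, 1]
  core[, nx + 1L] <- core[, nx + 1L] + core[, nx + 2L]
  out <- core[, 2:(nx + 1L), drop = FALSE]
  attr(out, "pixel_size_nm") <- bin_nm
  out
}
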