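## Shared image utilities: FFT cross-correlation registration, sub-pixel
## shifting, separable Gaussian blur with reflective borders, 2-D Gaussian
## peak fitting, bilinear sampling.

# Replace NA cells (edge stripes of cross-cumulant lattices) by replicating
# the previous valid value along the column, then along the row.
fill_edge_na <- function(img) {
  if (!anyNA(img)) return(img)
  fill_vec <- function(v) {
    idx <- which(!is.na(v))
    if (length(idx) == 0L) return(v)
    v[idx[pmax(1L, findInterval(seq_along(v), idx))]]
  }
  img <- apply(img, 2L, fill_vec)
  if (anyNA(img)) img <- t(apply(img, 1L, fill_vec))
  img
}

# Iterative local-mean fill for scattered NAs (used by flattening).
na_fill_local <- function(img, max_iter = 100L) {
  while (anyNA(img) && max_iter > 0L) {
    na_idx <- which(is.na(img), arr.ind = TRUE)
    filled <- apply(na_idx, 1L, function(rc) {
      r <- rc[1]; c <- rc[2]
      win <- img[max(1, r - 1):min(nrow(img), r + 1),
                 max(1, c - 1):min(ncol(img), c + 1)]
      if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
    })
    img[is.na(img)] <- filled
    max_iter <- max_iter - 1L
  }
  img
}

# Integer-peak cross-correlation shift (b relative to a) with parabolic
# sub-pixel refinement; positive dy/dx mean b is displaced down/right.
estimate_shift <- function(a, b, max_shift = 10L) {
  stopifnot(all(dim(a) == dim(b)))
  a <- fill_edge_na(a); b <- fill_edge_na(b)
  a <- a - mean(a); b <- b - mean(b)
  H <- nrow(a); W <- ncol(a)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  lag_r <- c(0:(H - 1)); lag_r[lag_r > H / 2] <- lag_r[lag_r > H / 2] - H
  lag_c <- c(0:(W - 1)); lag_c[lag_c > W / 2] <- lag_c[lag_c > W / 2] - W
  ok_r <- abs(lag_r) <= max_shift
  ok_c <- abs(lag_c) <= max_shift
  sub <- cc[ok_r, ok_c, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  dy0 <- -lag_r[ok_r][pk[1]]
  dx0 <- -lag_c[ok_c][pk[2]]
  # parabolic refinement on the full circular correlation surface, sampled
  # at integer lags around the peak
  at <- function(dr, dc) {
    r <- ((-(dy0 + dr)) %% H) + 1L
    c <- ((-(dx0 + dc)) %% W) + 1L
    cc[r, c]
  }
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den >= 0) return(0)
    d <- 0.5 * (m1 - p1) / den
    max(min(d, 0.5), -0.5)
  }
  c(dy0 + refine(at(-1, 0), at(0, 0), at(1, 0)),
    dx0 + refine(at(0, -1), at(0, 0), at(0, 1)))
}

# Bilinear shift of an image by (dy, dx); out-of-range samples replicate the
# border. Shifting by the estimated (dy, dx) aligns image b onto a.
shift_image <- function(img, dy, dx) {
  na_mask <- is.na(img)
  img <- fill_edge_na(img)
  H <- nrow(img); W <- ncol(img)
  yi <- seq_len(H) + dy
  xi <- seq_len(W) + dx
  y0 <- pmin(pmax(floor(yi), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xi), 1L), W); x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a00 <- img[y0, x0, drop = FALSE]; a10 <- img[y1, x0, drop = FALSE]
  a01 <- img[y0, x1, drop = FALSE]; a11 <- img[y1, x1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  out <- a00 * (1 - wy) * (1 - wx) + a10 * wy * (1 - wx) +
    a01 * (1 - wy) * wx + a11 * wy * wx
  out[na_mask] <- NA_real_
  out
}

gauss_kernel_1d <- function(sigma) {
  h <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with reflective boundary handling.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  h <- (length(k) - 1L) / 2L
  pad_reflect <- function(m, n) {
    top <- m[pmin(n:1, nrow(m)), , drop = FALSE]
    bot <- m[pmax(nrow(m) - (1:n) + 1L, 1L), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_cols <- function(m) {
    p <- pad_reflect(m, h)
    f <- stats::filter(p, k, method = "convolution", sides = 2)
    matrix(f[(h + 1L):(h + nrow(m)), ], nrow(m), ncol(m))
  }
  t(conv_cols(t(conv_cols(img))))
}

# Fit an isotropic 2-D Gaussian peak A*exp(-((x-x0)^2+(y-y0)^2)/(2 s^2)) + c
# to an image; returns the centre (row/col, 1-based), sigma (px), amplitude,
# offset and the implied FWHM in pixels.
fit_gaussian_peak <- function(img, init = NULL) {
  H <- nrow(img); W <- ncol(img)
  d <- data.frame(z = as.vector(img),
                  y = rep(seq_len(H), times = W),
                  x = rep(seq_len(W), each = H))
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  start <- list(A = max(img) - min(img), x0 = unname(pk[2]), y0 = unname(pk[1]),
                s = max(1, min(H, W) / 8), c0 = min(img))
  if (!is.null(init)) start[names(init)] <- init
  fit <- minpack.lm::nlsLM(
    z ~ A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2)) + c0,
    data = d, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- as.list(coef(fit))
  p$s <- abs(p$s)
  p$fwhm_px <- 2 * sqrt(2 * log(2)) * p$s
  p
}

# Bilinear sample of an image at continuous (row, col) positions (1-based
# pixel-centre coordinates).
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  r0 <- pmin(pmax(floor(rows), 1L), H); r1 <- pmin(r0 + 1L, H)
  c0 <- pmin(pmax(floor(cols), 1L), W); c1 <- pmin(c0 + 1L, W)
  fr <- pmin(pmax(rows - r0, 0), 1); fc <- pmin(pmax(cols - c0, 0), 1)
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

# Block-average an image by an integer factor per axis.
block_average <- function(img, factor) {
  factor <- as.integer(factor)
  H <- nrow(img) %/% factor * factor
  W <- ncol(img) %/% factor * factor
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  m <- matrix(img, nrow = factor)
  m <- colMeans(m)
  m <- matrix(m, nrow = H %/% factor)          # H/f x W
  m <- matrix(t(m), nrow = factor)             # average over column blocks
  t(matrix(colMeans(m), nrow = W %/% factor))
}
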