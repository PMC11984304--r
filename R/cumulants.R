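## Joint zero-lag cumulants and cumulant images.
##
## The order-n joint cumulant of time series X1..Xn is evaluated through the
## set-partition formula
##   kappa(X1..Xn) = sum_{partitions pi} (-1)^(|pi|-1) (|pi|-1)! prod_{B in pi}
##                   E[prod_{i in B} X_i],
## applied to mean-subtracted series, so partitions containing singleton
## blocks vanish and only partitions with all blocks of size >= 2 are
## enumerated. All moment estimators are biased (1/T), the standard SOFI
## normalization, so cumulant images are consistent across orders.

# Set partitions of 1..n via restricted growth strings.
# min_block_size = 2 drops partitions with singleton blocks.
set_partitions <- function(n, min_block_size = 1L) {
  stopifnot(n >= 1, n <= 8)
  key <- paste0("p", n, "_", min_block_size)
  cached <- .partition_cache[[key]]
  if (!is.null(cached)) return(cached)
  parts <- list()
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      sizes <- tabulate(rgs)
      if (min(sizes) >= min_block_size) {
        parts[[length(parts) + 1L]] <<- split(seq_len(n), rgs)
      }
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, 0L)
  .partition_cache[[key]] <- parts
  parts
}

.partition_cache <- new.env(parent = emptyenv())

# Encode the partitions of order n (blocks >= 2) for the C++ engine:
# block bitmasks, block counts per partition and the alternating weights.
partition_encoding <- function(n) {
  parts <- set_partitions(n, min_block_size = 2L)
  nblocks <- vapply(parts, length, integer(1))
  weights <- (-1)^(nblocks - 1L) * factorial(nblocks - 1L)
  masks <- unlist(lapply(parts, function(p) {
    vapply(p, function(b) sum(bitwShiftL(1L, b - 1L)), integer(1))
  }), use.names = FALSE)
  list(nblocks = as.integer(nblocks), masks = as.integer(masks),
       weights = as.numeric(weights))
}

#' Joint zero-lag cumulant of up to six time series
#'
#' Evaluates the order-n joint cumulant through the set-partition formula on
#' mean-subtracted series (equivalently, in terms of joint central moments).
#' With all slots holding the same series this is the order-n auto-cumulant;
#' for n = 2 it reduces to the (1/T-normalized) sample covariance.
#'
#' @param x numeric matrix with one column per series (T x n), or a list of
#'   equal-length numeric vectors, or a single vector (interpreted with
#'   `order` repeats).
#' @param order cumulant order when `x` is a single vector; otherwise taken
#'   from the number of columns. Must be in 1..6.
#' @return a single numeric value.
#' @examples
#' set.seed(1)
#' x <- rbinom(2000, 1, 0.25)
#' joint_cumulant(x, order = 2)  # approx 0.25 * 0.75
#' @export
joint_cumulant <- function(x, order = NULL) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1L) stop("series length mismatch")
    x <- do.call(cbind, x)
  }
  if (is.null(dim(x))) {
    if (is.null(order)) stop("`order` is required for a single series")
    x <- matrix(rep(as.numeric(x), order), ncol = order)
  }
  n <- ncol(x)
  if (n < 1L || n > 6L) stop("order must be in 1..6")
  if (nrow(x) < n) stop("series length must be at least the order")
  if (!all(is.finite(x))) stop("series must be finite")
  if (n == 1L) return(mean(x))
  xc <- sweep(x, 2L, colMeans(x))
  parts <- set_partitions(n, min_block_size = 2L)
  total <- 0
  for (p in parts) {
    b <- length(p)
    term <- (-1)^(b - 1L) * factorial(b - 1L)
    for (blk in p) {
      v <- xc[, blk[1L]]
      for (j in blk[-1L]) v <- v * xc[, j]
      term <- term * mean(v)
    }
    total <- total + term
  }
  total
}

# Central-moment expressions of the univariate cumulants, vectorized over
# pixels. `xc` is the centred T x P movie matrix.
auto_cumulant_from_central <- function(xc, order) {
  m <- function(k) colMeans(xc^k)
  switch(as.character(order),
    "1" = rep(0, ncol(xc)),
    "2" = m(2),
    "3" = m(3),
    "4" = m(4) - 3 * m(2)^2,
    "5" = m(5) - 10 * m(3) * m(2),
    "6" = {
      m2 <- m(2); m3 <- m(3)
      m(6) - 15 * m(4) * m2 - 10 * m3^2 + 30 * m2^3
    },
    stop("order must be in 1..6"))
}

new_cumulant_image <- function(values, order, oversampling, distance_factors,
                               pixel_size_nm, provenance = list()) {
  structure(list(values = values, order = order, oversampling = oversampling,
                 distance_factors = distance_factors,
                 pixel_size_nm = pixel_size_nm,
                 provenance = provenance),
            class = "cumulant_image")
}

#' @export
print.cumulant_image <- function(x, ...) {
  cat(sprintf("<cumulant_image> order %d, %d x %d lattice (oversampling %d), %s nm/px\n",
              x$order, nrow(x$values), ncol(x$values), x$oversampling,
              format(x$pixel_size_nm, digits = 4)))
  if (isTRUE(x$provenance$flattened)) cat("  flattened\n")
  if (!is.null(x$provenance$n_subsequences))
    cat(sprintf("  combined from %d subsequence(s)\n", x$provenance$n_subsequences))
  invisible(x)
}

#' Order-n auto-cumulant image
#'
#' Per camera pixel, the zero-lag cumulant of the pixel's own intensity time
#' series. The image lives on the camera grid (oversampling 1, all distance
#' factors 1). For an isolated emitter the image is the PSF raised to the
#' power n, i.e. a Gaussian PSF narrows by sqrt(n).
#'
#' @param movie a [movie_stack].
#' @param order cumulant order in 2..6.
#' @param frames optional integer vector of frame indices to use.
#' @return a `cumulant_image`.
#' @export
auto_cumulant_image <- function(movie, order, frames = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!(order %in% 2:6)) stop("order must be in 2..6")
  X <- movie$frames
  if (!is.null(frames)) X <- X[frames, , drop = FALSE]
  if (nrow(X) < 100 * order)
    warning(sprintf("only %d frames for order %d; at least %d recommended",
                    nrow(X), order, 100 * order))
  xc <- sweep(X, 2L, colMeans(X))
  vals <- matrix(auto_cumulant_from_central(xc, order),
                 nrow = movie$shape[1], ncol = movie$shape[2])
  new_cumulant_image(vals, order, 1L, matrix(1, nrow(vals), ncol(vals)),
                     movie$meta$pixel_size_nm,
                     provenance = list(kind = "auto", n_frames = nrow(X),
                                       lags = "zero"))
}

#' Order-n cross-cumulant image on an oversampled virtual-pixel lattice
#'
#' For every point of the camera grid refined n-fold, the combination of n
#' physical pixels whose centroid coincides with the point and which
#' minimizes the summed squared distance to the centroid (lexicographic
#' tie-break) is selected, and the joint cumulant of those pixel series is
#' computed. The Gaussian distance factor exp(-sum |r_i - rbar|^2 /
#' (2 sigma_eff^2)) is recorded per lattice point, with sigma_eff the
#' pixel-integration-corrected PSF width derived from the movie metadata.
#' Integer lattice points use the degenerate combination (the pixel repeated
#' n times) and therefore equal the auto-cumulant there. Lattice points whose
#' combination would require a pixel outside the frame are NA and are filled
#' during flattening.
#'
#' @param movie a [movie_stack].
#' @param order cumulant order in 2..6.
#' @param neighborhood_radius pixel search radius; the variance-minimizing
#'   combinations span at most 1 pixel, so values >= 1 are equivalent.
#'   Must be at least ceiling(order / 2) / order in pixels, i.e. >= 1.
#' @param frames optional integer vector of frame indices to use.
#' @return a `cumulant_image` with oversampling n.
#' @export
cross_cumulant_image <- function(movie, order, neighborhood_radius = 1L,
                                 frames = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  if (!(order %in% 2:6)) stop("order must be in 2..6")
  if (neighborhood_radius < 1L) stop("neighborhood_radius must be >= 1")
  H <- movie$shape[1]; W <- movie$shape[2]
  if (H < 2L || W < 2L) stop("movie smaller than the pixel neighborhood")
  X <- movie$frames
  if (!is.null(frames)) X <- X[frames, , drop = FALSE]
  xc <- sweep(X, 2L, colMeans(X))
  enc <- partition_encoding(order)
  vals <- cpp_cross_cumulant_values(xc, H, W, as.integer(order),
                                    enc$nblocks, enc$masks, enc$weights)
  vals <- matrix(vals, nrow = H * order, ncol = W * order)
  dist <- distance_factor_lattice(H, W, order, psf_sigma_eff_px(movie$meta))
  new_cumulant_image(vals, order, as.integer(order), dist,
                     movie$meta$pixel_size_nm / order,
                     provenance = list(kind = "cross", n_frames = nrow(X),
                                       lags = "zero"))
}

# Effective PSF sigma in camera pixels, including the 1/12 box-integration
# variance of the pixel area.
psf_sigma_eff_px <- function(meta) {
  sigma_px <- meta$psf_fwhm_nm / meta$pixel_size_nm / (2 * sqrt(2 * log(2)))
  sqrt(sigma_px^2 + 1 / 12)
}

# Closed-form distance factors: for residue k of n the x-coordinate multiset
# has k pixels at base+1 and n-k at base, so sum (x_i - xbar)^2 = k(n-k)/n.
distance_factor_lattice <- function(H, W, order, sigma_px) {
  n <- order
  k <- seq_len(n) - 1L
  s1d <- k * (n - k) / n
  rowS <- rep(s1d, length.out = H * n)[seq_len(H * n)]
  colS <- rep(s1d, length.out = W * n)[seq_len(W * n)]
  exp(-outer(rowS, colS, "+") / (2 * sigma_px^2))
}

#' Split a movie into consecutive subsequences
#'
#' Movies are processed in consecutive blocks of `block_length` frames
#' (default 1000, chosen to limit the influence of slow drifts within a
#' block); a movie shorter than one block forms a single block of its full
#' length, and remainder frames beyond the last full block are dropped so all
#' blocks share the same estimator variance.
#'
#' @param n_frames total number of frames (or a [movie_stack]).
#' @param block_length frames per subsequence.
#' @return object of class `subsequence_plan`: list of index ranges plus the
#'   number of dropped remainder frames.
#' @export
split_subsequences <- function(n_frames, block_length = 1000L) {
  if (inherits(n_frames, "movie_stack")) n_frames <- nrow(n_frames$frames)
  stopifnot(n_frames >= 1)
  if (n_frames < block_length) {
    blocks <- list(seq_len(n_frames))
    dropped <- 0L
  } else {
    nb <- n_frames %/% block_length
    blocks <- lapply(seq_len(nb), function(i)
      seq.int((i - 1L) * block_length + 1L, i * block_length))
    dropped <- n_frames - nb * block_length
  }
  structure(list(blocks = blocks, block_length = block_length,
                 dropped = dropped), class = "subsequence_plan")
}

#' Register and average per-subsequence cumulant images
#'
#' Each block's image is registered to the first block by maximizing the
#' cross-correlation (integer shift plus parabolic sub-pixel refinement),
#' shifted by bilinear interpolation, and the registered images are averaged.
#' When combining high-order images the shifts are usually estimated on the
#' corresponding order-2 images (higher SNR) and passed via `shifts`.
#'
#' @param images list of `cumulant_image`s of identical order and lattice.
#' @param shifts optional list of c(dy, dx) lattice-pixel shifts to apply
#'   (first entry implicitly zero may be included or omitted); when NULL the
#'   shifts are estimated from the images themselves.
#' @param max_shift integer search radius (lattice px) for shift estimation.
#' @return a `cumulant_image` with the applied shifts in the provenance.
#' @export
combine_subsequence_cumulants <- function(images, shifts = NULL,
                                          max_shift = 10L) {
  stopifnot(length(images) >= 1)
  ords <- vapply(images, function(i) i$order, numeric(1))
  if (length(unique(ords)) != 1L) stop("images differ in order")
  dims <- vapply(images, function(i) dim(i$values), numeric(2))
  if (any(dims != dims[, 1])) stop("images differ in lattice size")
  base <- images[[1]]
  if (length(images) == 1L) {
    base$provenance$n_subsequences <- 1L
    base$provenance$shifts <- list(c(0, 0))
    return(base)
  }
  if (is.null(shifts)) {
    shifts <- lapply(images, function(im)
      estimate_shift(base$values, im$values, max_shift = max_shift))
  } else {
    if (length(shifts) == length(images) - 1L)
      shifts <- c(list(c(0, 0)), shifts)
    stopifnot(length(shifts) == length(images))
  }
  reg <- mapply(function(im, sh) shift_image(im$values, sh[1], sh[2]),
                images, shifts, SIMPLIFY = FALSE)
  avg <- Reduce(`+`, reg) / length(reg)
  out <- base
  out$values <- avg
  out$provenance$n_subsequences <- length(images)
  out$provenance$shifts <- shifts
  out
}
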