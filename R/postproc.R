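## Postprocessing of raw cumulant images into display-ready SOFI
## reconstructions: distance-factor flattening, Richardson-Lucy
## deconvolution, brightness linearization, and the order-2..6 pipeline.

#' SOFI reconstruction configuration
#'
#' @param orders cumulant orders to reconstruct (subset of 2..6).
#' @param deconv_fwhm_px Gaussian deconvolution kernel FWHM on the
#'   camera-pixel scale (default 4.2 px); on an n-fold oversampled lattice
#'   the kernel is `deconv_fwhm_px * n` lattice units.
#' @param deconv_iterations Richardson-Lucy iteration count (default 10).
#' @param deconv_fwhm_mode `"fixed"` uses `deconv_fwhm_px` for every order;
#'   `"matched"` derives the kernel from the movie metadata as the width of
#'   the order-n cumulant PSF (`psf_fwhm / sqrt(n)` camera px).
#' @param linearize apply the signed n-th root after deconvolution.
#' @param reconvolve optionally re-blur with a Gaussian of
#'   `deconv_fwhm_px / sqrt(order)` px after the root (off by default).
#' @param block_length subsequence length in frames.
#' @param register apply inter-subsequence drift correction.
#' @return object of class `sofi_config`.
#' @export
sofi_config <- function(orders = c(2L, 3L, 4L),
                        deconv_fwhm_px = 4.2,
                        deconv_iterations = 10L,
                        deconv_fwhm_mode = c("fixed", "matched"),
                        linearize = TRUE,
                        reconvolve = FALSE,
                        block_length = 1000L,
                        register = TRUE) {
  deconv_fwhm_mode <- match.arg(deconv_fwhm_mode)
  if (deconv_iterations < 1) stop("deconv_iterations must be >= 1")
  if (deconv_fwhm_px <= 0) stop("deconv_fwhm_px must be > 0")
  if (!all(orders %in% 2:6)) stop("orders must be within 2..6")
  structure(list(orders = as.integer(orders),
                 deconv_fwhm_px = deconv_fwhm_px,
                 deconv_iterations = as.integer(deconv_iterations),
                 deconv_fwhm_mode = deconv_fwhm_mode,
                 linearize = linearize, reconvolve = reconvolve,
                 block_length = as.integer(block_length),
                 register = register),
            class = "sofi_config")
}

#' Flatten a cross-cumulant image
#'
#' Divides every virtual pixel by its Gaussian distance factor, equalizes the
#' residual lattice-parity gain (each of the n x n parity classes is divided
#' by the median ratio of its values to a smoothed reference image), and
#' fills missing lattice points by local interpolation. Flattening an
#' already-flattened (or oversampling-1) image is the identity.
#'
#' @param ci a `cumulant_image`.
#' @return the flattened `cumulant_image`.
#' @export
flatten <- function(ci) {
  stopifnot(inherits(ci, "cumulant_image"))
  if (isTRUE(ci$provenance$flattened)) return(ci)
  if (any(ci$distance_factors == 0, na.rm = TRUE))
    stop("zero distance factor: degenerate pixel combination")
  v <- ci$values / ci$distance_factors
  n <- ci$oversampling
  if (n > 1L) {
    FH <- nrow(v); FW <- ncol(v)
    ref <- gauss_blur(fill_edge_na(v), sigma = n)
    # pass 1: per parity class, subtract the additive offset visible in
    # low-signal regions (noise cumulants enter only combinations with
    # repeated pixels, imprinting an n-periodic comb on the background)
    dark <- ref < quantile(ref, 0.25)
    for (pr in seq_len(n) - 1L) {
      for (pc in seq_len(n) - 1L) {
        rows <- seq(pr + 1L, FH, by = n)
        cols <- seq(pc + 1L, FW, by = n)
        sub <- v[rows, cols, drop = FALSE]
        dk <- dark[rows, cols, drop = FALSE] & is.finite(sub)
        if (sum(dk) >= 10) {
          off <- median(sub[dk] - ref[rows, cols][dk])
          v[rows, cols] <- sub - off
        }
      }
    }
    # pass 2: per class, divide by a locally smoothed gain field relative to
    # a parity-agnostic reference smoothed over the same physical window
    # (removes the signal-proportional component of the comb)
    ref2 <- gauss_blur(fill_edge_na(v), sigma = 2 * n)
    eps <- 1e-6 * max(abs(ref2))
    for (pr in seq_len(n) - 1L) {
      for (pc in seq_len(n) - 1L) {
        rows <- seq(pr + 1L, FH, by = n)
        cols <- seq(pc + 1L, FW, by = n)
        sub <- fill_edge_na(v[rows, cols, drop = FALSE])
        rsub <- ref2[rows, cols, drop = FALSE]
        gain <- (gauss_blur(sub, 2) + eps) / (rsub + eps)
        gain <- pmin(pmax(gain, 0.2), 5)
        v[rows, cols] <- v[rows, cols] / gain
      }
    }
    v <- na_fill_local(v)
  }
  out <- ci
  out$values <- v
  out$distance_factors <- matrix(1, nrow(v), ncol(v))
  out$provenance$flattened <- TRUE
  out
}

#' Richardson-Lucy deconvolution with a Gaussian kernel
#'
#' Fixed iteration count, reflective image borders; the image must be
#' non-negative (apply the negativity policy first). Interior flux is
#' conserved by the RL multiplicative updates.
#'
#' @param image numeric matrix (non-negative).
#' @param fwhm_px Gaussian kernel FWHM in pixels of `image`.
#' @param iterations number of RL iterations.
#' @return deconvolved matrix.
#' @export
deconvolve <- function(image, fwhm_px, iterations = 10L) {
  if (all(image == 0)) {
    warning("all-zero image: returned unchanged")
    return(image)
  }
  if (any(image < 0)) stop("image must be non-negative for RL deconvolution")
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  est <- image
  eps <- 1e-12 * max(image)
  for (i in seq_len(iterations)) {
    conv <- gauss_blur(est, sigma)
    ratio <- image / pmax(conv, eps)
    est <- est * gauss_blur(ratio, sigma)
  }
  est
}

#' Brightness linearization (signed n-th root)
#'
#' An order-n cumulant scales with the n-th power of the emitter brightness;
#' the signed root `sign(v) * |v|^(1/n)` restores a linear brightness scale
#' (applied after deconvolution). Order 1 is the identity.
#'
#' @param image numeric matrix.
#' @param order cumulant order (>= 1).
#' @return linearized matrix.
#' @export
linearize <- function(image, order) {
  stopifnot(order >= 1)
  if (order == 1) return(image)
  sign(image) * abs(image)^(1 / order)
}

#' Full SOFI reconstruction pipeline
#'
#' Splits the movie into subsequences, computes per-block cross-cumulant
#' images for every requested order, estimates inter-subsequence drift on
#' the order-2 block images and applies the (rescaled) shifts to all orders,
#' averages, flattens, clips negatives for Richardson-Lucy deconvolution and
#' applies brightness linearization. Orders are processed independently:
#' a failure in one order is recorded in `$errors` and does not abort the
#' others.
#'
#' @param movie a [movie_stack].
#' @param config a [sofi_config].
#' @return object of class `sofi_result`: per-order list with the combined
#'   flattened `cumulant` (signed values retained), the final `image`, the
#'   deconvolution kernel used, plus `plan` and `errors`.
#' @export
sofi_pipeline <- function(movie, config = sofi_config()) {
  stopifnot(inherits(movie, "movie_stack"))
  plan <- split_subsequences(nrow(movie$frames), config$block_length)
  orders <- sort(unique(c(2L, config$orders)))  # order 2 drives registration
  block_images <- list()
  for (n in orders) {
    block_images[[as.character(n)]] <- tryCatch(
      lapply(plan$blocks, function(idx)
        cross_cumulant_image(movie, n, frames = idx)),
      error = function(e) e)
  }
  shifts_cam <- NULL
  b2 <- block_images[["2"]]
  if (config$register && length(plan$blocks) > 1 && !inherits(b2, "error")) {
    shifts_cam <- lapply(b2, function(im)
      estimate_shift(b2[[1]]$values, im$values, max_shift = 10L) / 2)
  }
  result <- list()
  errors <- list()
  for (n in config$orders) {
    key <- as.character(n)
    res <- tryCatch({
      blocks <- block_images[[key]]
      if (inherits(blocks, "error")) stop(blocks$message)
      sh <- if (!is.null(shifts_cam))
        lapply(shifts_cam, function(s) s * n) else NULL
      comb <- combine_subsequence_cumulants(blocks, shifts = sh)
      flat <- flatten(comb)
      fwhm_cam <- if (config$deconv_fwhm_mode == "matched")
        movie$meta$psf_fwhm_nm / movie$meta$pixel_size_nm / sqrt(n)
      else config$deconv_fwhm_px
      kernel_fwhm <- fwhm_cam * flat$oversampling
      img <- pmax(flat$values, 0)
      img <- deconvolve(img, kernel_fwhm, config$deconv_iterations)
      if (config$linearize) img <- linearize(img, n)
      if (isTRUE(config$reconvolve))
        img <- gauss_blur(img, config$deconv_fwhm_px / sqrt(n) *
                            flat$oversampling / (2 * sqrt(2 * log(2))))
      list(cumulant = flat, image = img,
           pixel_size_nm = flat$pixel_size_nm,
           kernel_fwhm_lattice_px = kernel_fwhm,
           provenance = c(flat$provenance,
                          list(deconv_iterations = config$deconv_iterations,
                               linearized = config$linearize)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      result[[key]] <- res
    }
  }
  structure(list(orders = result, errors = errors, plan = plan,
                 config = config,
                 pixel_size_nm = movie$meta$pixel_size_nm),
            class = "sofi_result")
}

#' @export
print.sofi_result <- function(x, ...) {
  cat(sprintf("<sofi_result> orders: %s\n",
              paste(names(x$orders), collapse = ", ")))
  if (length(x$errors))
    cat(sprintf("  failed orders: %s\n", paste(names(x$errors), collapse = ", ")))
  invisible(x)
}
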