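## Multi-position grid acquisition simulation and mosaic stitching.

#' Plan a multi-position acquisition grid
#'
#' Tiles are laid out in raster order with nominal stage steps of
#' `tile size x (1 - overlap)` pixels, mirroring a motorized-stage
#' multiposition protocol (e.g. a 4 x 9 grid at 10% overlap).
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param tile_shape_px c(rows, cols) of one tile in camera pixels.
#' @param overlap overlap fraction between adjacent tiles, in (0, 0.5).
#' @return object of class `grid_plan`: tile table with nominal pixel
#'   offsets (x right, y down) in raster order.
#' @export
plan_grid <- function(rows, cols, tile_shape_px = c(64L, 64L),
                      overlap = 0.10) {
  stopifnot(rows >= 1, cols >= 1)
  if (overlap <= 0 || overlap >= 0.5)
    stop("overlap must be in (0, 0.5)")
  step_y <- tile_shape_px[1] * (1 - overlap)
  step_x <- tile_shape_px[2] * (1 - overlap)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  tiles <- data.frame(tile = seq_len(nrow(g)), row = g$row, col = g$col,
                      offset_x_px = (g$col - 1) * step_x,
                      offset_y_px = (g$row - 1) * step_y)
  structure(list(rows = rows, cols = cols,
                 tile_shape_px = as.integer(tile_shape_px),
                 overlap = overlap, order = "raster", tiles = tiles),
            class = "grid_plan")
}

#' Simulate the tile movies of a grid acquisition
#'
#' Each tile is rendered from the large phantom restricted to its stage
#' window. Sites in overlap strips appear in multiple tiles with independent
#' blinking realizations (tiles are imaged sequentially). Gaussian stage
#' jitter (default SD 2 px) is added to the nominal offsets so stitching
#' refinement is exercised; the realized offsets are returned as ground
#' truth.
#'
#' @param large_phantom a [phantom] covering the full grid footprint.
#' @param grid_plan a [grid_plan].
#' @param optics an [optics_camera]; `n_frames` applies per tile.
#' @param jitter_sd_px stage positioning error SD in pixels (0 disables).
#' @param seed master seed for jitter and per-tile acquisition streams.
#' @return list with `movies` (list of [movie_stack]), `true_offsets_px`
#'   (data.frame of realized x/y offsets) and the plan.
#' @export
simulate_tiles <- function(large_phantom, grid_plan, optics,
                           jitter_sd_px = 2, seed = 1L) {
  stopifnot(inherits(large_phantom, "phantom"),
            inherits(grid_plan, "grid_plan"))
  ps <- optics$pixel_size_nm
  ts <- grid_plan$tile_shape_px
  tiles <- grid_plan$tiles
  foot_x <- (max(tiles$offset_x_px) + ts[2]) * ps
  foot_y <- (max(tiles$offset_y_px) + ts[1]) * ps
  if (foot_x > large_phantom$extent_nm[1] + 1e-6 ||
      foot_y > large_phantom$extent_nm[2] + 1e-6)
    stop("grid footprint exceeds the phantom extent")
  set.seed(as.integer(seed))
  jit <- matrix(rnorm(2 * nrow(tiles), 0, jitter_sd_px), ncol = 2)
  if (jitter_sd_px == 0) jit[] <- 0
  movies <- vector("list", nrow(tiles))
  true_off <- data.frame(tile = tiles$tile,
                         x_px = tiles$offset_x_px + jit[, 1],
                         y_px = tiles$offset_y_px + jit[, 2])
  for (i in seq_len(nrow(tiles))) {
    ox_nm <- true_off$x_px[i] * ps
    oy_nm <- true_off$y_px[i] * ps
    sites <- large_phantom$sites
    inside <- sites$x_nm >= ox_nm & sites$x_nm < ox_nm + ts[2] * ps &
      sites$y_nm >= oy_nm & sites$y_nm < oy_nm + ts[1] * ps
    sub <- sites[inside, , drop = FALSE]
    sub$x_nm <- sub$x_nm - ox_nm
    sub$y_nm <- sub$y_nm - oy_nm
    tile_ph <- phantom(sub, extent_nm = c(ts[2], ts[1]) * ps,
                       kinetics = large_phantom$kinetics,
                       structure_label = sprintf("tile_%d", i))
    tile_optics <- optics
    tile_optics$seed <- child_seed(seed, "tile", i)
    movies[[i]] <- render_movie(tile_ph, tile_optics)
  }
  list(movies = movies, true_offsets_px = true_off, plan = grid_plan)
}

#' Stitch tile images into a mosaic
#'
#' Tiles are placed in raster order; each tile after the first is refined
#' against the already-composited canvas by normalized cross-correlation
#' over its nominal overlap region (integer search up to `search_px` plus
#' parabolic sub-pixel refinement; a featureless overlap falls back to the
#' nominal offset with a warning). Seams are blended with linear feathering.
#'
#' @param tile_images list of equally sized image matrices in raster order.
#' @param grid_plan the [grid_plan] (its nominal offsets are the starting
#'   point).
#' @param search_px integer refinement search radius in pixels; it must
#'   cover the worst-case relative stage error between a tile and the
#'   already-composited canvas (for Gaussian jitter of SD s px, the
#'   tile-to-tile difference has SD s * sqrt(2), so the default covers
#'   beyond 3 sigma of the default jitter model).
#' @return list with `image` (the mosaic), `offsets_px` (data.frame of
#'   refined x/y offsets) and `refined` logical per tile.
#' @export
stitch <- function(tile_images, grid_plan, search_px = 10L) {
  stopifnot(length(tile_images) >= 1)
  tiles <- grid_plan$tiles
  stopifnot(length(tile_images) == nrow(tiles))
  th <- nrow(tile_images[[1]]); tw <- ncol(tile_images[[1]])
  scale_y <- th / grid_plan$tile_shape_px[1]   # images may be oversampled
  scale_x <- tw / grid_plan$tile_shape_px[2]
  off <- data.frame(tile = tiles$tile,
                    x_px = tiles$offset_x_px * scale_x,
                    y_px = tiles$offset_y_px * scale_y)
  refined <- rep(FALSE, nrow(tiles))
  pad <- 2L * search_px + 4L        # jittered tiles may start before origin
  off$x_px <- off$x_px + pad
  off$y_px <- off$y_px + pad
  ch <- ceiling(max(off$y_px) + th + pad)
  cw <- ceiling(max(off$x_px) + tw + pad)
  canvas <- matrix(0, ch, cw)
  weight <- matrix(0, ch, cw)
  feather <- feather_weights(th, tw,
                             round(grid_plan$overlap * c(th, tw)))
  place <- function(canvas, weight, img, oy, ox) {
    r0 <- round(oy); c0 <- round(ox)
    sub_img <- shift_image(img, -(oy - r0), -(ox - c0))  # sub-pixel residual
    rr <- (r0 + 1):(r0 + th); cc <- (c0 + 1):(c0 + tw)
    canvas[rr, cc] <- canvas[rr, cc] + sub_img * feather
    weight[rr, cc] <- weight[rr, cc] + feather
    list(canvas = canvas, weight = weight)
  }
  # pass 1: sequential raster placement, each tile refined against the
  # canvas composited so far
  canvas[] <- 0; weight[] <- 0
  for (i in seq_along(tile_images)) {
    img <- tile_images[[i]]
    ox <- off$x_px[i]; oy <- off$y_px[i]
    if (i > 1) {
      sh <- refine_tile_offset(canvas, weight, img, oy, ox, search_px)
      if (!is.null(sh)) {
        oy <- sh[1]; ox <- sh[2]
        refined[i] <- TRUE
      } else {
        warning(sprintf("tile %d: featureless overlap, nominal offset kept", i))
      }
      off$x_px[i] <- ox; off$y_px[i] <- oy
    }
    st <- place(canvas, weight, img, oy, ox)
    canvas <- st$canvas; weight <- st$weight
  }
  # pass 2 (run twice): leave-one-out re-registration against the full
  # composite, breaking the chain-error accumulation of the raster pass;
  # tiles that fell back in pass 1 get the full search radius, since their
  # placement may still carry the whole stage error
  if (length(tile_images) > 2) {
    for (sweep in 1:2) {
      for (i in seq_along(tile_images)[-1]) {
        canvas[] <- 0; weight[] <- 0
        for (j in seq_along(tile_images)) {
          if (j == i) next
          st <- place(canvas, weight, tile_images[[j]],
                      off$y_px[j], off$x_px[j])
          canvas <- st$canvas; weight <- st$weight
        }
        radius <- if (refined[i]) min(search_px, 3L) else search_px
        sh <- refine_tile_offset(canvas, weight, tile_images[[i]],
                                 off$y_px[i], off$x_px[i], radius)
        if (!is.null(sh)) {
          off$y_px[i] <- sh[1]
          off$x_px[i] <- sh[2]
          refined[i] <- TRUE
        }
      }
    }
  }
  # final composition at the refined offsets
  canvas[] <- 0; weight[] <- 0
  for (i in seq_along(tile_images)) {
    st <- place(canvas, weight, tile_images[[i]], off$y_px[i], off$x_px[i])
    canvas <- st$canvas; weight <- st$weight
  }
  mosaic <- canvas
  pos <- weight > 0
  mosaic[pos] <- canvas[pos] / weight[pos]
  used_r <- range(which(rowSums(weight) > 0))
  used_c <- range(which(colSums(weight) > 0))
  list(image = mosaic[used_r[1]:used_r[2], used_c[1]:used_c[2]],
       offsets_px = data.frame(tile = off$tile,
                               x_px = (off$x_px - pad) / scale_x,
                               y_px = (off$y_px - pad) / scale_y),
       # position of image pixel (1, 1) in the offset coordinate frame
       origin_px = c(x = (used_c[1] - 1 - pad) / scale_x,
                     y = (used_r[1] - 1 - pad) / scale_y),
       refined = refined)
}

# Linear feather: weight ramps from 1/(w+1) to 1 across `border` pixels.
feather_weights <- function(th, tw, border) {
  ramp <- function(n, b) {
    b <- max(1L, b)
    w <- rep(1, n)
    edge <- seq_len(b) / (b + 1)
    w[seq_len(b)] <- edge
    w[n + 1 - seq_len(b)] <- rev(edge)
    w
  }
  outer(ramp(th, border[1]), ramp(tw, border[2]))
}

# NCC refinement of one tile against the composited canvas; returns the
# refined absolute c(oy, ox) position, or NULL when the overlap carries no
# structure. Every candidate integer placement extracts its own canvas
# window, so a tile whose true position slid its overlap away from the
# nominal placement is still found within the search radius.
refine_tile_offset <- function(canvas, weight, img, oy, ox, search_px) {
  th <- nrow(img); tw <- ncol(img)
  r0 <- round(oy); c0 <- round(ox)
  # masked smoothing: blur(masked values)/blur(mask) denoises without
  # bleeding content from outside the overlap, and applies identically to
  # both sides, so exactly matching content stays exactly matching
  window_at <- function(dy, dx) {
    rr <- (r0 + dy + 1):(r0 + dy + th)
    cc <- (c0 + dx + 1):(c0 + dx + tw)
    if (rr[1] < 1 || cc[1] < 1 || rr[th] > nrow(canvas) ||
        cc[tw] > ncol(canvas)) return(NULL)
    wsub <- weight[rr, cc]
    mask <- wsub > 0
    if (sum(mask) < 50) return(NULL)
    csub <- canvas[rr, cc]
    csub[mask] <- csub[mask] / wsub[mask]
    csub[!mask] <- 0
    bm <- pmax(gauss_blur(mask * 1, 0.8), 1e-9)
    list(mask = mask, bm = bm,
         csub_s = gauss_blur(csub * mask, 0.8) / bm)
  }
  scores <- matrix(NA_real_, 2 * search_px + 1, 2 * search_px + 1)
  for (dy in -search_px:search_px) {
    for (dx in -search_px:search_px) {
      w <- window_at(dy, dx)
      if (is.null(w)) next
      b <- (gauss_blur(img * w$mask, 0.8) / w$bm)[w$mask]
      a <- w$csub_s[w$mask]
      if (sd(a) == 0 || sd(b) == 0) next
      scores[dy + search_px + 1, dx + search_px + 1] <- stats::cor(a, b)
    }
  }
  if (all(is.na(scores))) return(NULL)
  if (max(scores, na.rm = TRUE) < 0.5) return(NULL)  # featureless overlap
  pk <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  dy <- pk[1] - search_px - 1L
  dx <- pk[2] - search_px - 1L
  w <- window_at(dy, dx)
  mask <- w$mask
  csub_s <- w$csub_s
  smooth_tile <- function(m) gauss_blur(m * mask, 0.8) / w$bm
  # sub-pixel stage: gradient-based (Lucas-Kanade style) least squares with
  # a linear intensity map, iterated on bilinearly shifted tile content;
  # exactly matching content converges to the integer optimum immediately
  gy <- 0; gx <- 0
  H <- nrow(img); W <- ncol(img)
  interior <- matrix(FALSE, H, W)
  interior[2:(H - 1), 2:(W - 1)] <- TRUE
  for (iter in 1:3) {
    sh_img <- smooth_tile(shift_image(img, -gy, -gx))
    Gy <- (rbind(sh_img[-1, , drop = FALSE], sh_img[H, , drop = FALSE]) -
             rbind(sh_img[1, , drop = FALSE], sh_img[-H, , drop = FALSE])) / 2
    Gx <- (cbind(sh_img[, -1, drop = FALSE], sh_img[, W, drop = FALSE]) -
             cbind(sh_img[, 1, drop = FALSE], sh_img[, -W, drop = FALSE])) / 2
    ok <- mask & interior
    if (sum(ok) < 50) break
    X <- cbind(1, sh_img[ok], Gy[ok], Gx[ok])
    fit <- tryCatch(qr.coef(qr(X), csub_s[ok]), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit)) || abs(fit[2]) < 1e-12) break
    step_y <- -fit[3] / fit[2]
    step_x <- -fit[4] / fit[2]
    step_y <- max(min(step_y, 0.75), -0.75)
    step_x <- max(min(step_x, 0.75), -0.75)
    gy <- gy + step_y; gx <- gx + step_x
    if (max(abs(c(step_y, step_x))) < 1e-3) break
  }
  gy <- max(min(gy, 1), -1); gx <- max(min(gx, 1), -1)
  # the window at the scored placement sees the tile content displaced by
  # (gy, gx) relative to that placement, so the refined absolute origin is
  # the scored integer position plus the measured sub-pixel displacement
  c(r0 + dy + gy, c0 + dx + gx)
}

# Integer shift with NA padding (content moves down/right for positive
# shifts).
shift_int <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  sr <- max(1, 1 + dy):min(H, H + dy)
  sc <- max(1, 1 + dx):min(W, W + dx)
  out[sr, sc] <- img[sr - dy, sc - dx]
  out
}
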