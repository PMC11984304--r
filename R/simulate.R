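## Stochastic DNA-PAINT blinking simulation: alternating-renewal binding
## traces per motif, exact frame integration of the occupancy, PSF rendering
## with pixel-integrated Gaussians, and sCMOS noise.

#' Simulate the binding trace of one docking site
#'
#' Each of the `n_repeat_motifs` motifs is an independent alternating renewal
#' process: exponential unbound dwells with mean `1/per_site_binding_rate`
#' and exponential bound dwells with mean
#' `mean_bound_time * destabilizer_on_time_factor`. Simultaneous occupancy of
#' distinct motifs is allowed by default and sums as multi-emitter
#' brightness; with `allow_simultaneous = FALSE` overlapping intervals are
#' merged so at most one imager counts at a time.
#'
#' @param kinetics a [kinetic_params].
#' @param duration_s trace duration in seconds (> 0).
#' @param seed RNG seed.
#' @param start_bound if TRUE every motif starts in the bound state at t = 0
#'   (useful for rendering an "always on" emitter when `mean_bound_time`
#'   far exceeds the movie).
#' @param allow_simultaneous allow overlapping occupancy of distinct motifs.
#' @return object of class `binding_trace`: data.frame with columns `motif`,
#'   `t_bind`, `t_unbind` (seconds, clipped to `[0, duration_s]`, sorted by
#'   `t_bind`), with the kinetics and duration as attributes.
#' @export
simulate_binding_trace <- function(kinetics, duration_s, seed = 1L,
                                   start_bound = FALSE,
                                   allow_simultaneous = TRUE) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be finite and > 0")
  mean_off <- 1 / kinetics$per_site_binding_rate
  mean_on <- kinetics$mean_bound_time * kinetics$destabilizer_on_time_factor
  if (!is.finite(mean_off) || !is.finite(mean_on))
    stop("non-finite dwell-time means")
  set.seed(as.integer(seed))
  out <- vector("list", kinetics$n_repeat_motifs)
  for (m in seq_len(kinetics$n_repeat_motifs)) {
    bind <- numeric(0); unbind <- numeric(0)
    t <- 0; first <- TRUE
    repeat {
      n_draw <- max(16L,
                    ceiling((duration_s - t) / (mean_on + mean_off) * 1.5) + 8L)
      offd <- rexp(n_draw, rate = 1 / mean_off)
      ond <- rexp(n_draw, rate = 1 / mean_on)
      if (first && isTRUE(start_bound)) offd[1] <- 0
      first <- FALSE
      starts <- t + cumsum(offd) + c(0, cumsum(ond))[seq_len(n_draw)]
      ends <- starts + ond
      bind <- c(bind, starts); unbind <- c(unbind, ends)
      t <- ends[n_draw]
      if (t >= duration_s) break
    }
    keep <- bind < duration_s
    if (any(keep)) {
      out[[m]] <- data.frame(motif = m, t_bind = bind[keep],
                             t_unbind = pmin(unbind[keep], duration_s))
    }
  }
  df <- if (length(out)) do.call(rbind, out) else NULL
  if (is.null(df))
    df <- data.frame(motif = integer(0), t_bind = numeric(0),
                     t_unbind = numeric(0))
  df <- df[order(df$t_bind), , drop = FALSE]
  rownames(df) <- NULL
  if (!allow_simultaneous && nrow(df) > 1) df <- merge_intervals(df)
  structure(df, class = c("binding_trace", "data.frame"),
            kinetics = kinetics, duration_s = duration_s,
            allow_simultaneous = allow_simultaneous)
}

# Union-merge overlapping intervals (at most one emitter at a time).
merge_intervals <- function(df) {
  df <- df[order(df$t_bind), , drop = FALSE]
  keep_b <- df$t_bind[1]; keep_u <- df$t_unbind[1]
  bs <- numeric(0); us <- numeric(0)
  for (i in seq_len(nrow(df))[-1]) {
    if (df$t_bind[i] <= keep_u) {
      keep_u <- max(keep_u, df$t_unbind[i])
    } else {
      bs <- c(bs, keep_b); us <- c(us, keep_u)
      keep_b <- df$t_bind[i]; keep_u <- df$t_unbind[i]
    }
  }
  bs <- c(bs, keep_b); us <- c(us, keep_u)
  data.frame(motif = rep(1L, length(bs)), t_bind = bs, t_unbind = us)
}

#' Integrate a binding trace over camera frames
#'
#' Exact interval arithmetic: element t of the returned series is the total
#' bound time (summed over motifs) intersecting the frame window
#' `[(t-1) * frame_time, t * frame_time)`; no sub-frame time binning is
#' involved, so the series sums exactly to the total clipped bound time.
#'
#' @param trace a `binding_trace` (or data.frame with `t_bind`, `t_unbind`).
#' @param frame_time frame integration time in seconds (> 0).
#' @param n_frames number of frames.
#' @return numeric vector of emitter-seconds per frame, length `n_frames`.
#' @export
integrate_occupancy <- function(trace, frame_time, n_frames) {
  if (frame_time <= 0) stop("frame_time must be > 0")
  occ <- numeric(n_frames)
  if (nrow(trace) == 0) return(occ)
  t_end <- n_frames * frame_time
  a <- pmax(trace$t_bind, 0)
  b <- pmin(trace$t_unbind, t_end)
  keep <- b > a
  a <- a[keep]; b <- b[keep]
  if (!length(a)) return(occ)
  f0 <- pmax(floor(a / frame_time), 0)
  f1 <- pmin(ceiling(b / frame_time) - 1, n_frames - 1)
  f1 <- pmax(f1, f0)
  add <- function(idx, val) {
    agg <- rowsum(val, idx)
    at <- as.integer(rownames(agg))
    occ[at] <<- occ[at] + agg[, 1]
  }
  single <- f1 == f0
  if (any(single)) add(f0[single] + 1L, (b - a)[single])
  multi <- !single
  if (any(multi)) {
    add(f0[multi] + 1L, (f0[multi] + 1) * frame_time - a[multi])
    add(f1[multi] + 1L, b[multi] - f1[multi] * frame_time)
    # full middle frames as a difference array
    span <- f1[multi] - f0[multi] - 1L
    has_mid <- span > 0L
    if (any(has_mid)) {
      delta <- numeric(n_frames + 1L)
      first_mid <- f0[multi][has_mid] + 2L        # 1-based first full frame
      after_last <- f1[multi][has_mid] + 1L       # 1-based frame past the run
      agg_s <- rowsum(rep(frame_time, length(first_mid)), first_mid)
      delta[as.integer(rownames(agg_s))] <-
        delta[as.integer(rownames(agg_s))] + agg_s[, 1]
      agg_e <- rowsum(rep(frame_time, length(after_last)), after_last)
      keep_e <- as.integer(rownames(agg_e)) <= n_frames + 1L
      delta[as.integer(rownames(agg_e))[keep_e]] <-
        delta[as.integer(rownames(agg_e))[keep_e]] - agg_e[keep_e, 1]
      occ <- occ + cumsum(delta)[seq_len(n_frames)]
    }
  }
  occ
}

#' Render a DNA-PAINT blinking movie from a phantom
#'
#' Per frame, the expected photon image is the sum over sites of
#' occupancy (emitter-seconds) x photon rate x a 2-D Gaussian PSF integrated
#' over each pixel area (erf differences, not centre sampling), plus the
#' uniform diffusive-imager background scaled by the illumination-mode
#' factor. Observed counts are
#' `round(gain * Poisson(expected) + Normal(0, read_noise) + offset)`,
#' clipped at zero. One master seed drives deterministic per-site child
#' streams (adding a site does not perturb the other sites' traces) and a
#' separate noise stream.
#'
#' @param phantom a [phantom]; sites falling outside the field are dropped
#'   with a warning.
#' @param optics an [optics_camera].
#' @param noise apply the camera noise model; if FALSE the expected photon
#'   image (plus offset, scaled by gain) is returned un-rounded.
#' @param start_bound start every motif bound at t = 0.
#' @param keep_traces attach the per-site binding traces (attribute
#'   `"traces"`) for ground-truth comparisons.
#' @param allow_simultaneous passed to [simulate_binding_trace()].
#' @return object of class `movie_stack`: list with `frames` (T x P matrix,
#'   pixels column-major with `P = prod(shape)`), `shape` c(rows, cols) and
#'   `meta`.
#' @export
render_movie <- function(phantom, optics, noise = TRUE, start_bound = FALSE,
                         keep_traces = FALSE, allow_simultaneous = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(optics, "optics_camera"))
  ps <- optics$pixel_size_nm
  W <- max(1L, round(phantom$extent_nm[1] / ps))
  H <- max(1L, round(phantom$extent_nm[2] / ps))
  T_ <- optics$n_frames
  bg <- optics$background_photons_per_pixel_per_frame *
    .illumination_background_factor[[optics$illumination_mode]]
  if (nrow(phantom$sites) == 0 && bg <= 0)
    stop("empty phantom with zero background: nothing to render")
  sites <- phantom$sites
  inside <- sites$x_nm >= 0 & sites$x_nm < W * ps &
    sites$y_nm >= 0 & sites$y_nm < H * ps
  if (any(!inside)) {
    warning(sprintf("%d site(s) outside the field were dropped",
                    sum(!inside)))
    sites <- sites[inside, , drop = FALSE]
  }
  sigma_px <- optics$psf_fwhm_nm / ps / (2 * sqrt(2 * log(2)))
  halfw <- ceiling(4 * sigma_px + 1)
  duration <- T_ * optics$frame_time_s
  expected <- matrix(bg, nrow = T_, ncol = H * W)
  traces <- if (keep_traces) vector("list", nrow(sites)) else NULL
  for (i in seq_len(nrow(sites))) {
    tr <- simulate_binding_trace(
      phantom$kinetics, duration,
      seed = child_seed(optics$seed, "site", sites$site_id[i]),
      start_bound = start_bound, allow_simultaneous = allow_simultaneous)
    if (keep_traces) traces[[i]] <- tr
    if (nrow(tr) == 0) next
    occ <- integrate_occupancy(tr, optics$frame_time_s, T_)
    if (all(occ == 0)) next
    # pixel-integrated PSF profiles (erf differences), separable in x and y
    cx <- sites$x_nm[i] / ps   # pixel units, origin at field corner
    cy <- sites$y_nm[i] / ps
    c0 <- max(0L, floor(cx) - halfw); c1 <- min(W - 1L, floor(cx) + halfw)
    r0 <- max(0L, floor(cy) - halfw); r1 <- min(H - 1L, floor(cy) + halfw)
    px <- diff(stats::pnorm((seq(c0, c1 + 1) - cx) / sigma_px))
    py <- diff(stats::pnorm((seq(r0, r1 + 1) - cy) / sigma_px))
    patch <- as.vector(outer(py, px))  # rows vary fastest, matching column-major images
    cols_idx <- as.vector(outer((r0:r1) + 1L, (c0:c1) * H, "+"))
    rate <- optics$photons_per_bound_imager_per_s
    expected[, cols_idx] <- expected[, cols_idx] +
      (occ * rate) %*% t(patch)
  }
  if (noise) {
    set.seed(child_seed(optics$seed, "noise"))
    counts <- optics$camera_gain * rpois(length(expected), expected) +
      rnorm(length(expected), 0, optics$read_noise_sd) + optics$camera_offset
    frames <- matrix(pmax(round(counts), 0), nrow = T_)
  } else {
    frames <- optics$camera_gain * expected + optics$camera_offset
  }
  meta <- c(unclass(optics),
            list(phantom_label = phantom$structure_label, shape = c(H, W)))
  out <- structure(list(frames = frames, shape = c(H, W), meta = meta),
                   class = "movie_stack")
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("<movie_stack> %d frames of %d x %d px (%.0f nm/px, %.0f ms/frame)\n",
              nrow(x$frames), x$shape[1], x$shape[2],
              x$meta$pixel_size_nm, 1000 * x$meta$frame_time_s))
  invisible(x)
}

#' Extract one frame of a movie as a matrix
#' @param movie a `movie_stack`.
#' @param t frame index.
#' @return rows x cols numeric matrix.
#' @export
movie_frame <- function(movie, t) {
  matrix(movie$frames[t, ], nrow = movie$shape[1], ncol = movie$shape[2])
}

#' Temporal mean image of a movie
#' @param movie a `movie_stack`.
#' @return rows x cols numeric matrix.
#' @export
mean_image <- function(movie) {
  matrix(colMeans(movie$frames), nrow = movie$shape[1], ncol = movie$shape[2])
}

#' Summary statistics of binding traces
#'
#' Estimates the mean on-time (bound dwell), the mean off-time (per-motif
#' gaps between successive binding events), the event rate and the duty
#' cycle (fraction of the trace with at least one motif bound). With no
#' events the estimators are returned as NA with `n_events = 0`, flagged
#' `undefined`.
#'
#' @param traces a `binding_trace` or a list of them.
#' @return list with `mean_on_s`, `mean_off_s`, `events_per_s`,
#'   `duty_cycle`, `n_events`, `undefined`.
#' @export
binding_statistics <- function(traces) {
  if (inherits(traces, "binding_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  ons <- numeric(0); offs <- numeric(0)
  n_events <- 0L; total_time <- 0; bound_time <- 0
  for (tr in traces) {
    dur <- attr(tr, "duration_s")
    total_time <- total_time + dur
    n_events <- n_events + nrow(tr)
    if (nrow(tr) == 0) next
    ons <- c(ons, tr$t_unbind - tr$t_bind)
    for (m in unique(tr$motif)) {
      sub <- tr[tr$motif == m, , drop = FALSE]
      if (nrow(sub) > 1)
        offs <- c(offs, sub$t_bind[-1] - sub$t_unbind[-nrow(sub)])
    }
    merged <- merge_intervals(tr)
    bound_time <- bound_time + sum(merged$t_unbind - merged$t_bind)
  }
  undefined <- n_events == 0L
  list(mean_on_s = if (undefined) NA_real_ else mean(ons),
       mean_off_s = if (length(offs)) mean(offs) else NA_real_,
       events_per_s = n_events / total_time,
       duty_cycle = bound_time / total_time,
       n_events = n_events, undefined = undefined)
}
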