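## Ground-truth phantoms: docking-site positions plus shared kinetics.
## Coordinates are sample-frame nm, origin at the field corner; camera pixel
## (0,0) covers [0, pixel_size)^2 and emitter positions are continuous.

#' Construct a phantom from explicit docking-site positions
#'
#' @param sites data.frame with columns `x_nm`, `y_nm` (and optionally
#'   `site_id`).
#' @param extent_nm field size c(width, height) in nm.
#' @param kinetics shared [kinetic_params] for all sites.
#' @param structure_label free-text description of the structure.
#' @param truth_geometry parametric ground-truth description (e.g. filament
#'   vertex lists) kept for accuracy checks.
#' @return object of class `phantom`.
#' @export
phantom <- function(sites, extent_nm, kinetics,
                    structure_label = "custom", truth_geometry = list()) {
  stopifnot(is.data.frame(sites), inherits(kinetics, "kinetic_params"))
  if (nrow(sites) > 0) {
    stopifnot(all(c("x_nm", "y_nm") %in% names(sites)))
    if (!all(is.finite(sites$x_nm)) || !all(is.finite(sites$y_nm)))
      stop("site positions must be finite")
  }
  if (is.null(sites$site_id)) sites$site_id <- seq_len(nrow(sites))
  structure(list(sites = sites, extent_nm = extent_nm, kinetics = kinetics,
                 structure_label = structure_label,
                 truth_geometry = truth_geometry),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s: %d sites in %.0f x %.0f nm\n",
              x$structure_label, nrow(x$sites),
              x$extent_nm[1], x$extent_nm[2]))
  invisible(x)
}

#' Random filament phantom
#'
#' Draws smooth random curves (constant-speed paths whose heading performs a
#' small-step random walk, steered back at the field borders) and decorates
#' them with docking sites at exponential arc-length spacings, i.e. a Poisson
#' point process of the requested linear density along each curve.
#' Microtubule-like samples correspond to densities of roughly 0.02-0.1
#' sites/nm.
#'
#' @param n_filaments number of curves (>= 0; 0 gives an empty phantom).
#' @param extent_nm field size c(width, height) nm.
#' @param site_linear_density sites per nm of arc length (> 0).
#' @param kinetics shared [kinetic_params].
#' @param curvature heading random-walk standard deviation per 100 nm step
#'   (radians); 0 gives straight filaments.
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @param margin_nm border kept clear of curve vertices.
#' @return a `phantom` whose `truth_geometry$filaments` holds the vertex
#'   paths.
#' @export
make_filament_phantom <- function(n_filaments, extent_nm = c(6400, 6400),
                                  site_linear_density = 0.05,
                                  kinetics = kinetic_params(),
                                  curvature = 0.15, seed = 1L,
                                  margin_nm = 400) {
  stopifnot(site_linear_density > 0, n_filaments >= 0)
  step <- 100
  if (extent_nm[1] <= 2 * margin_nm + 2 * step)
    stop("extent width too small to place a curve")
  if (extent_nm[2] <= 2 * margin_nm + 2 * step)
    stop("extent height too small to place a curve")
  set.seed(as.integer(seed))
  curves <- vector("list", n_filaments)
  all_sites <- list()
  for (f in seq_len(n_filaments)) {
    n_steps <- ceiling(1.5 * max(extent_nm) / step)
    x <- runif(1, margin_nm, extent_nm[1] - margin_nm)
    y <- runif(1, margin_nm, extent_nm[2] - margin_nm)
    theta <- runif(1, 0, 2 * pi)
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- x; ys[1] <- y
    for (i in seq_len(n_steps)) {
      theta <- theta + rnorm(1, 0, curvature)
      # steer back toward the field centre near the border
      cx <- extent_nm[1] / 2 - x; cy <- extent_nm[2] / 2 - y
      near <- min(x, extent_nm[1] - x, y, extent_nm[2] - y) < margin_nm
      if (near) {
        target <- atan2(cy, cx)
        d <- atan2(sin(target - theta), cos(target - theta))
        theta <- theta + 0.5 * d
      }
      x <- min(max(x + step * cos(theta), 0), extent_nm[1])
      y <- min(max(y + step * sin(theta), 0), extent_nm[2])
      xs[i + 1] <- x; ys[i + 1] <- y
    }
    curves[[f]] <- cbind(x_nm = xs, y_nm = ys)
    seglen <- sqrt(diff(xs)^2 + diff(ys)^2)
    arclen <- c(0, cumsum(seglen))
    total <- arclen[length(arclen)]
    # Poisson process along arc length
    pos <- numeric(0); s <- 0
    repeat {
      s <- s + rexp(1, rate = site_linear_density)
      if (s > total) break
      pos <- c(pos, s)
    }
    if (length(pos) > 0) {
      sx <- approx(arclen, xs, xout = pos)$y
      sy <- approx(arclen, ys, xout = pos)$y
      all_sites[[f]] <- data.frame(x_nm = sx, y_nm = sy, filament = f)
    }
  }
  sites <- if (length(all_sites)) do.call(rbind, all_sites) else
    data.frame(x_nm = numeric(0), y_nm = numeric(0), filament = integer(0))
  phantom(sites, extent_nm, kinetics, structure_label = "filaments",
          truth_geometry = list(filaments = curves,
                                site_linear_density = site_linear_density,
                                curvature = curvature, seed = seed))
}

#' Two-point resolution test phantom
#'
#' Two docking sites symmetric about the field centre, separated by
#' `separation_nm` along x. Both sites share the `kinetics` object by
#' reference.
#'
#' @param separation_nm centre-to-centre distance in nm (>= 0).
#' @param kinetics shared [kinetic_params].
#' @param extent_nm field size c(width, height) nm.
#' @return a `phantom`.
#' @export
make_point_pair_phantom <- function(separation_nm,
                                    kinetics = kinetic_params(),
                                    extent_nm = c(3200, 3200)) {
  stopifnot(separation_nm >= 0)
  cx <- extent_nm[1] / 2; cy <- extent_nm[2] / 2
  sites <- data.frame(x_nm = cx + c(-0.5, 0.5) * separation_nm,
                      y_nm = c(cy, cy))
  phantom(sites, extent_nm, kinetics, structure_label = "point_pair",
          truth_geometry = list(separation_nm = separation_nm,
                                center_nm = c(cx, cy)))
}

#' Line-lattice phantom with guaranteed field coverage
#'
#' Two families of parallel straight filaments (default +40 and -40 degrees)
#' with evenly spaced intercepts, decorated with Poisson-distributed docking
#' sites. Unlike [make_filament_phantom()]'s random curves, the lattice
#' guarantees structure in every part of the field, which matters for
#' stitching registration targets spanning multi-tile mosaics.
#'
#' @param extent_nm field size c(width, height) nm.
#' @param spacing_nm distance between parallel lines within a family.
#' @param angles_deg orientations of the line families.
#' @param site_linear_density sites per nm of line length.
#' @param kinetics shared [kinetic_params].
#' @param seed RNG seed for the Poisson site placement.
#' @return a `phantom` with `truth_geometry$lines` holding the segment
#'   endpoints.
#' @export
make_line_lattice_phantom <- function(extent_nm, spacing_nm = 2000,
                                      angles_deg = c(40, -40),
                                      site_linear_density = 0.05,
                                      kinetics = kinetic_params(),
                                      seed = 1L) {
  stopifnot(spacing_nm > 0, site_linear_density > 0)
  set.seed(as.integer(seed))
  W <- extent_nm[1]; H <- extent_nm[2]
  diag_len <- sqrt(W^2 + H^2)
  segs <- list(); sites <- list()
  for (ang in angles_deg) {
    th <- ang * pi / 180
    d <- c(cos(th), sin(th))              # line direction
    nvec <- c(-sin(th), cos(th))          # normal
    offs <- seq(-diag_len / 2, diag_len / 2, by = spacing_nm)
    for (o in offs) {
      c0 <- c(W, H) / 2 + o * nvec
      ts <- c(-diag_len, diag_len)
      # clip the parametric line c0 + t*d to the extent
      for (dim in 1:2) {
        lim <- c(0, c(W, H)[dim])
        if (abs(d[dim]) > 1e-12) {
          t_pair <- sort((lim - c0[dim]) / d[dim])
          ts <- c(max(ts[1], t_pair[1]), min(ts[2], t_pair[2]))
        } else if (c0[dim] < lim[1] || c0[dim] > lim[2]) {
          ts <- c(0, 0)
        }
      }
      if (ts[2] <= ts[1]) next
      p1 <- c0 + ts[1] * d; p2 <- c0 + ts[2] * d
      len <- ts[2] - ts[1]
      segs[[length(segs) + 1L]] <- c(p1, p2)
      pos <- numeric(0); s <- 0
      repeat {
        s <- s + rexp(1, rate = site_linear_density)
        if (s > len) break
        pos <- c(pos, s)
      }
      if (length(pos)) {
        sites[[length(sites) + 1L]] <-
          data.frame(x_nm = p1[1] + pos * d[1], y_nm = p1[2] + pos * d[2])
      }
    }
  }
  df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(x_nm = numeric(0), y_nm = numeric(0))
  keep <- df$x_nm >= 0 & df$x_nm < W & df$y_nm >= 0 & df$y_nm < H
  phantom(df[keep, , drop = FALSE], extent_nm, kinetics,
          structure_label = "line_lattice",
          truth_geometry = list(lines = segs, spacing_nm = spacing_nm,
                                angles_deg = angles_deg, seed = seed))
}

#' Uniform dense-site phantom
#'
#' One docking site at the centre of every camera pixel; used to check the
#' homogeneity of flattened cross-cumulant lattices.
#'
#' @param shape_px c(rows, cols) of the camera field.
#' @param pixel_size_nm camera pixel size in nm.
#' @param kinetics shared [kinetic_params].
#' @return a `phantom`.
#' @export
make_uniform_phantom <- function(shape_px, pixel_size_nm = 100,
                                 kinetics = kinetic_params()) {
  g <- expand.grid(row = seq_len(shape_px[1]) - 0.5,
                   col = seq_len(shape_px[2]) - 0.5)
  sites <- data.frame(x_nm = g$col * pixel_size_nm,
                      y_nm = g$row * pixel_size_nm)
  phantom(sites, extent_nm = c(shape_px[2], shape_px[1]) * pixel_size_nm,
          kinetics, structure_label = "uniform_grid")
}
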