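## File formats: multipage TIFF movies with plain-text metadata sidecars,
## 32-bit float TIFF reconstructions, ThunderSTORM-compatible localization
## CSV, TileConfiguration-style tile lists.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".meta.txt")

#' Write a movie as multipage 16-bit TIFF plus metadata sidecar
#'
#' One TIFF page per frame, 16-bit unsigned; acquisition metadata (pixel
#' size, frame time, gain, offset, read noise, PSF width, illumination mode,
#' seed) goes to a plain-text key = value sidecar next to the TIFF.
#'
#' @param movie a [movie_stack] with integer counts in 0..65535.
#' @param path output TIFF path.
#' @return the TIFF path, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  if (any(movie$frames < 0) || any(movie$frames > 65535) ||
      any(movie$frames != round(movie$frames)))
    stop("frames must hold integer counts in 0..65535 for 16-bit TIFF")
  pages <- lapply(seq_len(nrow(movie$frames)), function(t)
    movie_frame(movie, t) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- movie$meta
  keys <- c("pixel_size_nm", "psf_fwhm_nm", "frame_time_s", "n_frames",
            "photons_per_bound_imager_per_s",
            "background_photons_per_pixel_per_frame", "illumination_mode",
            "camera_gain", "camera_offset", "read_noise_sd", "seed",
            "phantom_label")
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format(meta[[k]], digits = 17, scientific = FALSE)),
    character(1))
  writeLines(lines, sidecar_path(path))
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; the sidecar is looked up next to it. A missing
#'   sidecar yields default metadata with a warning.
#' @return a [movie_stack].
#' @export
read_movie <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("malformed TIFF '%s': %s", path,
                                   conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (is.null(dim(pages[[i]])) || length(dim(pages[[i]])) != 2)
      stop(sprintf("malformed TIFF page %d in '%s'", i, path))
  }
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  frames <- t(vapply(pages, as.vector, numeric(H * W)))
  if (length(pages) == 1L) frames <- matrix(frames, nrow = 1)
  meta <- list(pixel_size_nm = 100, psf_fwhm_nm = 320, frame_time_s = 0.01,
               n_frames = length(pages),
               photons_per_bound_imager_per_s = NA_real_,
               background_photons_per_pixel_per_frame = NA_real_,
               illumination_mode = "TIRF", camera_gain = 1,
               camera_offset = 0, read_noise_sd = 0, seed = NA_integer_,
               phantom_label = "unknown")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    for (ln in readLines(sp)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) next
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  } else {
    warning(sprintf("no metadata sidecar at '%s'; using defaults", sp))
  }
  meta$shape <- c(H, W)
  structure(list(frames = frames, shape = c(H, W), meta = meta),
            class = "movie_stack")
}

#' Write a reconstruction or cumulant image as 32-bit TIFF
#'
#' Real-valued images are stored as 32-bit samples normalized to [0, 1];
#' the affine intensity map (`value_min`, `value_max`) goes to the sidecar
#' together with the lattice convention (fine-lattice point (0,0) coincides
#' with camera pixel centre (0,0)), order and oversampling, so
#' [read_image_tiff()] restores the original values to 2^-32 relative
#' precision.
#'
#' @param image a `cumulant_image` or plain matrix.
#' @param path output TIFF path.
#' @param meta optional extra sidecar fields.
#' @return the path, invisibly.
#' @export
write_image_tiff <- function(image, path, meta = list()) {
  if (inherits(image, "cumulant_image")) {
    meta <- c(meta, list(order = image$order,
                         oversampling = image$oversampling,
                         pixel_size_nm = image$pixel_size_nm,
                         lattice_origin = "camera_pixel_center_00"))
    image <- image$values
  }
  img <- image
  img[!is.finite(img)] <- 0
  lo <- min(img); hi <- max(img)
  span <- if (hi > lo) hi - lo else 1
  meta <- c(meta, list(value_min = lo, value_max = hi))
  tiff::writeTIFF((img - lo) / span, path, bits.per.sample = 32,
                  compression = "none", reduce = FALSE)
  lines <- vapply(names(meta), function(k)
    sprintf("%s = %s", k, format(meta[[k]], digits = 17)), character(1))
  writeLines(lines, sidecar_path(path))
  invisible(path)
}

#' Read a 32-bit TIFF image written by [write_image_tiff()]
#' @param path TIFF path.
#' @return numeric matrix with the original intensity scale restored
#'   (sidecar fields as attributes).
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  sp <- sidecar_path(path)
  meta <- list()
  if (file.exists(sp)) {
    for (ln in readLines(sp)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) {
        num <- suppressWarnings(as.numeric(trimws(kv[2])))
        meta[[trimws(kv[1])]] <- if (!is.na(num)) num else trimws(kv[2])
      }
    }
  }
  if (!is.null(meta$value_min) && !is.null(meta$value_max)) {
    span <- meta$value_max - meta$value_min
    if (span <= 0) span <- 1
    img <- img * span + meta$value_min
  }
  for (k in setdiff(names(meta), c("value_min", "value_max")))
    attr(img, k) <- meta[[k]]
  img
}

.loc_header <- c("frame", "x [nm]", "y [nm]", "sigma [nm]",
                 "intensity [photon]", "offset [photon]",
                 "uncertainty [nm]")

#' Write a localization table as ThunderSTORM-compatible CSV
#' @param table a `localization_table`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_localizations <- function(table, path) {
  df <- data.frame(table$frame, table$x_nm, table$y_nm, table$sigma_nm,
                   table$intensity, table$background, table$uncertainty_nm,
                   check.names = FALSE)
  names(df) <- .loc_header
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a localization CSV (tolerant to column reordering)
#' @param path CSV path with a ThunderSTORM-style header.
#' @param pixel_size_nm optional pixel size attribute to attach.
#' @return a `localization_table`.
#' @export
read_localizations <- function(path, pixel_size_nm = NULL) {
  df <- read.csv(path, check.names = FALSE)
  pick <- function(name) {
    i <- which(names(df) == name)
    if (length(i) == 0) stop(sprintf("missing column '%s'", name))
    df[[i[1]]]
  }
  out <- data.frame(frame = pick("frame"),
                    x_nm = pick("x [nm]"), y_nm = pick("y [nm]"),
                    sigma_nm = pick("sigma [nm]"),
                    intensity = pick("intensity [photon]"),
                    background = pick("offset [photon]"),
                    uncertainty_nm = pick("uncertainty [nm]"))
  structure(out, class = c("localization_table", "data.frame"),
            pixel_size_nm = pixel_size_nm)
}

#' Write a TileConfiguration-style tile list
#' @param offsets data.frame with `tile`, `x_px`, `y_px`.
#' @param filenames tile image file names.
#' @param path output text path.
#' @return the path, invisibly.
#' @export
write_tile_configuration <- function(offsets, filenames, path) {
  stopifnot(nrow(offsets) == length(filenames))
  lines <- c("# Define the number of dimensions we are working on",
             "dim = 2", "", "# Define the image coordinates")
  lines <- c(lines, sprintf("%s; ; (%.4f, %.4f)", filenames,
                            offsets$x_px, offsets$y_px))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TileConfiguration-style tile list
#' @param path text path.
#' @return data.frame with `file`, `x_px`, `y_px`.
#' @export
read_tile_configuration <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl(";", lines, fixed = TRUE)]
  parts <- strsplit(lines, ";")
  data.frame(
    file = trimws(vapply(parts, `[`, character(1), 1)),
    x_px = as.numeric(sub(".*\\(([-0-9.eE+]+),.*", "\\1", lines)),
    y_px = as.numeric(sub(".*,\\s*([-0-9.eE+]+)\\)\\s*$", "\\1", lines)))
}
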