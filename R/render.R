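#' Optics configuration of the synthetic backlit camera
#'
#' Per-pixel intensity follows Beer-Lambert attenuation through the circular
#' channel: `I = I0 * 10^(-OD)`, with `OD = od_full * c * chord / chord_ref`
#' where `chord = 2 sqrt((d/2)^2 - r^2)` is the light path through the
#' channel at radial offset `r` from the centerline and `chord_ref` the
#' largest channel diameter. Thrombus pixels are rendered near-opaque.
#' Additive Gaussian noise (fraction of the backlight level) and 16-bit
#' quantization complete the camera model.
#'
#' @param I0 backlight intensity in camera counts (16-bit range).
#' @param od_full optical density at concentration 1 through the reference
#'   chord.
#' @param noise_sd_frac noise standard deviation as a fraction of `I0`.
#' @param thrombus_transmittance fraction of `I0` transmitted by thrombus
#'   material.
#' @return an `optics_config` list.
#' @export
optics_config <- function(I0 = 60000, od_full = 1.2, noise_sd_frac = 0.005,
                          thrombus_transmittance = 0.03) {
  list(I0 = I0, od_full = od_full, noise_sd_frac = noise_sd_frac,
       thrombus_transmittance = thrombus_transmittance)
}

# per-channel-pixel optical path factor (chord / chord_ref), plus the pixel
# bookkeeping shared by rendering and analysis
.pixel_optics <- function(layout, maps) {
  idx <- which(maps$channel_mask)
  seg <- maps$segment_labels[idx]
  tab <- segment_table(layout)
  d <- tab$diameter_um[match(seg, tab$id)]
  off <- maps$offset_um[idx]
  chord <- 2 * sqrt(pmax((d / 2)^2 - off^2, 0))
  chord_ref <- max(tab$diameter_um)
  list(channel_idx = idx, segment = seg, station_um = maps$station_um[idx],
       path_factor = chord / chord_ref, diameter_um = d)
}

#' Render video frames from a transport field
#'
#' Maps control-volume concentrations to channel pixels, applies the
#' Beer-Lambert camera model and returns a `frame_stack`. Channel pixels are
#' stored as a compact (time x pixel) matrix; [as_frame_array] materializes
#' the full (time, rows, cols) array with glass pixels at the backlight
#' level.
#'
#' @param layout a `chip_layout`.
#' @param maps matching `segment_maps`.
#' @param field a `transport_field` whose recorded times are the frame times.
#' @param thrombi list of `microthrombus` (their footprints render
#'   near-opaque); may be empty.
#' @param optics an [optics_config].
#' @param timestamps frame times (s); defaults to the field's record times.
#' @param noise add Gaussian camera noise (default TRUE).
#' @param noise_seed seed of the noise substream.
#' @return a `frame_stack`.
#' @export
render_frames <- function(layout, maps, field, thrombi = list(),
                          optics = optics_config(), timestamps = NULL,
                          noise = TRUE, noise_seed = 1L) {
  if (is.null(timestamps)) timestamps <- field$times
  if (length(timestamps) != nrow(field$conc))
    stop("field does not cover the requested timestamps")
  po <- .pixel_optics(layout, maps)
  grid <- field$grid
  cv_of_px <- .cv_index_vec(grid, po$segment, po$station_um)
  conc_px <- field$conc[, cv_of_px, drop = FALSE]    # time x pixel
  I <- optics$I0 * 10^(-(optics$od_full * sweep(conc_px, 2, po$path_factor, "*")))
  fp_all <- unique(unlist(lapply(thrombi, function(t) t$footprint)))
  if (length(fp_all)) {
    cols <- match(fp_all, po$channel_idx)
    I[, cols] <- optics$I0 * optics$thrombus_transmittance
  }
  if (noise && optics$noise_sd_frac > 0) {
    .with_seed(noise_seed, {
      I <- I + rnorm(length(I), sd = optics$noise_sd_frac * optics$I0)
    })
  }
  I <- round(pmin(pmax(I, 0), 65535))
  frame_stack(values = I, channel_idx = po$channel_idx,
              image_shape = maps$image_shape, timestamps = timestamps,
              pixel_scale_um = maps$pixel_scale_um, background = optics$I0)
}

#' Render uniform-concentration calibration frames
#'
#' The clean chip (no thrombi) filled with dye at known uniform levels, used
#' to fit per-pixel calibration curves. Level 0 doubles as the clean-chip
#' reference for thrombus detection.
#'
#' @param layout,maps,optics as in [render_frames].
#' @param levels dye levels in `[0, 1]`.
#' @param reps frames per level (averaged during fitting).
#' @param noise,noise_seed camera noise controls.
#' @return a `frame_stack` whose `levels` field labels each frame.
#' @export
render_calibration_frames <- function(layout, maps, optics = optics_config(),
                                      levels = c(0, 0.25, 0.5, 0.75, 1),
                                      reps = 3, noise = TRUE, noise_seed = 2L) {
  po <- .pixel_optics(layout, maps)
  lv <- rep(levels, each = reps)
  I <- optics$I0 * 10^(-(optics$od_full * outer(lv, po$path_factor)))
  if (noise && optics$noise_sd_frac > 0) {
    .with_seed(noise_seed, {
      I <- I + rnorm(length(I), sd = optics$noise_sd_frac * optics$I0)
    })
  }
  I <- round(pmin(pmax(I, 0), 65535))
  fs <- frame_stack(values = I, channel_idx = po$channel_idx,
                    image_shape = maps$image_shape,
                    timestamps = seq_along(lv) - 1,
                    pixel_scale_um = maps$pixel_scale_um,
                    background = optics$I0)
  fs$levels <- lv
  fs
}

.cv_index_vec <- function(grid, segment, station_um) {
  i <- match(segment, grid$segment_ids)
  first <- grid$segment_first_cv[i]
  k <- grid$segment_n_cv[i]
  dx_um <- grid$cv_dx[first] * 1e6
  as.integer(first + pmin(pmax(floor(station_um / dx_um), 0), k - 1))
}

#' Time-ordered grayscale frame container
#'
#' Channel-pixel representation of a backlit recording: a (time x channel
#' pixel) intensity matrix plus the linear indices of the channel pixels in
#' the full raster. Glass pixels carry the constant backlight level and are
#' reconstructed on demand.
#'
#' @param values numeric/integer matrix, frames in rows.
#' @param channel_idx linear pixel indices (column-major, as `which()` on the
#'   mask).
#' @param image_shape integer (rows, cols).
#' @param timestamps frame times in seconds relative to infusion start.
#' @param pixel_scale_um um per pixel.
#' @param background glass intensity level.
#' @return a `frame_stack`.
#' @export
frame_stack <- function(values, channel_idx, image_shape, timestamps,
                        pixel_scale_um, background) {
  stopifnot(nrow(values) == length(timestamps),
            ncol(values) == length(channel_idx))
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(values = values, channel_idx = as.integer(channel_idx),
                 image_shape = as.integer(image_shape),
                 timestamps = as.numeric(timestamps),
                 pixel_scale_um = pixel_scale_um, background = background),
            class = "frame_stack")
}

#' Materialize a frame stack as a dense (time, rows, cols) array
#'
#' @param fs a `frame_stack`.
#' @param frames optional subset of frame indices.
#' @return numeric array (time, rows, cols); glass pixels at the background
#'   level.
#' @export
as_frame_array <- function(fs, frames = seq_along(fs$timestamps)) {
  rows <- fs$image_shape[1]; cols <- fs$image_shape[2]
  out <- array(fs$background, dim = c(length(frames), rows, cols))
  for (k in seq_along(frames)) {
    img <- matrix(fs$background, rows, cols)
    img[fs$channel_idx] <- fs$values[frames[k], ]
    out[k, , ] <- img
  }
  out
}

#' Build a frame stack from a dense array
#'
#' @param arr array (time, rows, cols).
#' @param mask logical channel mask (rows x cols); when NULL every pixel is
#'   kept.
#' @param timestamps frame times (s).
#' @param pixel_scale_um um per pixel.
#' @param background glass intensity (default: median border intensity of
#'   the first frame).
#' @return a `frame_stack`.
#' @export
frame_stack_from_array <- function(arr, mask = NULL, timestamps,
                                   pixel_scale_um,
                                   background = NULL) {
  rows <- dim(arr)[2]; cols <- dim(arr)[3]
  if (is.null(mask)) mask <- matrix(TRUE, rows, cols)
  idx <- which(mask)
  vals <- matrix(0, dim(arr)[1], length(idx))
  for (k in seq_len(dim(arr)[1])) {
    img <- arr[k, , ]
    vals[k, ] <- img[idx]
  }
  if (is.null(background)) {
    img1 <- arr[1, , ]
    background <- stats::median(img1[!mask])
  }
  frame_stack(vals, idx, c(rows, cols), timestamps, pixel_scale_um, background)
}

#' Write / read a frame stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' @param fs a `frame_stack`.
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `read_frame_stack` returns a `frame_stack`.
#' @export
write_frame_stack <- function(fs, path) {
  pages <- lapply(seq_along(fs$timestamps), function(k) {
    img <- matrix(fs$background, fs$image_shape[1], fs$image_shape[2])
    img[fs$channel_idx] <- fs$values[k, ]
    img / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(timestamps = fs$timestamps, pixel_scale_um = fs$pixel_scale_um,
               background = fs$background, levels = fs$levels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @param mask logical channel mask used to re-compact the pixels; when NULL
#'   every pixel is kept.
#' @export
read_frame_stack <- function(path, mask = NULL) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- length(meta$timestamps)
  # read page chunks so long recordings never materialize in full
  first <- tiff::readTIFF(path, all = 1L)[[1]]
  rows <- nrow(first); cols <- ncol(first)
  if (is.null(mask)) mask <- matrix(TRUE, rows, cols)
  idx <- which(mask)
  vals <- matrix(0, n, length(idx))
  chunk <- 200L
  for (start in seq(1L, n, by = chunk)) {
    pages <- tiff::readTIFF(path, all = start:min(start + chunk - 1L, n))
    for (k in seq_along(pages))
      vals[start + k - 1L, ] <- round(pages[[k]][idx] * 65535)
    rm(pages)
  }
  fs <- frame_stack(vals, idx, c(rows, cols), meta$timestamps,
                    meta$pixel_scale_um, background = meta$background)
  if (!is.null(meta$levels)) fs$levels <- meta$levels
  fs
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("frame_stack:", length(x$timestamps), "frames,",
      length(x$channel_idx), "channel pixels of",
      prod(x$image_shape), "; t =", x$timestamps[1], "..",
      x$timestamps[length(x$timestamps)], "s\n")
  invisible(x)
}
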