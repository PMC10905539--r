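#' Extract the channel area from a recording
#'
#' With a known chip layout the mask is the rasterized layout (bench and
#' camera are rigidly mounted; registration is identity). Without a layout
#' the mean pre-infusion frame is thresholded: channel pixels are darker than
#' glass under backlight, and connected components below `min_area` px are
#' dropped.
#'
#' @param frames a `frame_stack` (needs at least one pre-infusion frame).
#' @param layout optional `chip_layout`.
#' @param threshold_frac channel/glass separation as a fraction of the glass
#'   level (default 0.02).
#' @param min_area minimum component area in px.
#' @return logical channel mask (rows x cols).
#' @export
extract_channel_mask <- function(frames, layout = NULL, threshold_frac = 0.02,
                                 min_area = 16) {
  if (!is.null(layout)) return(rasterize_layout(layout)$channel_mask)
  pre <- which(frames$timestamps < 0)
  if (!length(pre)) stop("extraction error: no pre-infusion frames")
  rows <- frames$image_shape[1]; cols <- frames$image_shape[2]
  mean_img <- matrix(frames$background, rows, cols)
  mean_img[frames$channel_idx] <- colMeans(frames$values[pre, , drop = FALSE])
  glass <- frames$background
  cand <- mean_img < glass * (1 - threshold_frac)
  if (!any(cand)) stop("extraction error: empty channel mask")
  idx <- which(cand)
  comp <- label8_cpp(((idx - 1) %% rows) + 1L, ((idx - 1) %/% rows) + 1L, rows)
  keep <- comp %in% which(tabulate(comp) >= min_area)
  mask <- matrix(FALSE, rows, cols)
  mask[idx[keep]] <- TRUE
  if (!any(mask)) stop("extraction error: empty channel mask")
  mask
}

#' Fit per-pixel calibration curves
#'
#' For every channel pixel, the mean intensity at each known uniform dye
#' level defines the knots of a piecewise-linear monotone map from intensity
#' to concentration. Pixels whose mean response is not strictly monotone in
#' the level (flat optical path, dead pixels) are flagged invalid and drop
#' out of the analysis mask.
#'
#' A pixel is also invalidated when its full-scale response span (level 0 to
#' level 1) is below `min_span_frac` of its clean intensity: at the extreme
#' channel edge the optical path vanishes, the whole dye range spans only a
#' few camera counts, and inverting such a pixel amplifies camera noise past
#' the 20% classification threshold.
#'
#' @param cal_frames a `frame_stack` with a `levels` field labelling each
#'   frame (from [render_calibration_frames] or a sidecar).
#' @param known_levels the distinct levels to use, in `[0, 1]`, including 0.
#' @param mask optional logical mask restricting the fitted pixels.
#' @param min_span_frac minimum full-scale response span as a fraction of
#'   the pixel's level-0 intensity.
#' @return a `calibration_model`: `levels`, `intensity` (level x pixel mean
#'   intensities), `valid`, `channel_idx`, `image_shape`.
#' @export
fit_calibration <- function(cal_frames, known_levels = sort(unique(cal_frames$levels)),
                            mask = NULL, min_span_frac = 0.08) {
  if (is.null(cal_frames$levels)) stop("calibration stack carries no level labels")
  known_levels <- sort(known_levels)
  if (length(known_levels) < 2) stop("config error: need at least 2 calibration levels")
  if (any(known_levels < 0 | known_levels > 1)) stop("levels must lie in [0, 1]")
  keep_px <- if (is.null(mask)) seq_along(cal_frames$channel_idx)
             else which(cal_frames$channel_idx %in% which(mask))
  intensity <- t(vapply(known_levels, function(lv) {
    rows <- which(cal_frames$levels == lv)
    colMeans(cal_frames$values[rows, keep_px, drop = FALSE])
  }, numeric(length(keep_px))))
  # strictly monotone response required (either direction)
  dI <- apply(intensity, 2, diff)
  if (is.null(dim(dI))) dI <- matrix(dI, nrow = 1)
  monotone <- apply(dI, 2, function(d) all(d < 0) || all(d > 0))
  span <- abs(intensity[nrow(intensity), ] - intensity[1, ])
  valid <- monotone & span >= min_span_frac * pmax(intensity[1, ], 1)
  structure(list(levels = known_levels, intensity = intensity,
                 valid = valid,
                 channel_idx = cal_frames$channel_idx[keep_px],
                 image_shape = cal_frames$image_shape),
            class = "calibration_model")
}

#' Invert a recording to a per-pixel concentration stack
#'
#' Applies the per-pixel piecewise-linear calibration to every frame and
#' clamps to `[0, 1]`: intensities beyond the level-1 knot map to exactly 1,
#' beyond the level-0 knot to exactly 0. Interpolation between knots runs in
#' the log-intensity (optical density) domain, where exponential
#' (Beer-Lambert) attenuation is linear in concentration; intensity-domain
#' chords would read systematically high between knots. Invalid calibration
#' pixels are excluded (NA columns); thrombus pixels can be excluded
#' afterwards via the classification helpers.
#'
#' @param frames a `frame_stack`.
#' @param model a `calibration_model` fitted on the same optics.
#' @param mask optional logical mask further restricting pixels.
#' @return a `concentration_stack`.
#' @export
concentration_series <- function(frames, model, mask = NULL) {
  cols <- match(frames$channel_idx, model$channel_idx)
  if (anyNA(cols)) stop("input error: frames contain pixels the model was not fitted on")
  nlev <- length(model$levels)
  nk <- model$intensity[, cols, drop = FALSE]
  dec <- nk[1, ] > nk[nlev, ]   # intensity decreasing with level (absorbing dye)
  # orient all pixels as decreasing with level
  nk[, !dec] <- nk[nlev:1, !dec, drop = FALSE]
  v <- model$valid[cols]
  if (!is.null(mask)) v <- v & (frames$channel_idx %in% which(mask))
  # interpolate level against log-intensity (optical density): transmitted
  # intensity falls exponentially with concentration, so the OD-domain
  # piecewise-linear map is exact between knots instead of biased high
  out <- invert_calibration_cpp(log(pmax(frames$values, 0.5)),
                                log(pmax(nk, 0.5)), model$levels, v)
  # non-absorbing pixels were inverted against reflected knots
  if (any(!dec)) out[, !dec] <- 1 - out[, !dec]
  concentration_stack(out, frames$channel_idx, frames$image_shape,
                      frames$timestamps, valid = v)
}

#' Concentration stack container
#'
#' @param values (time x channel pixel) concentrations in `[0, 1]`, NA on
#'   invalid pixels.
#' @param channel_idx linear raster indices of the pixels.
#' @param image_shape integer (rows, cols).
#' @param timestamps frame times (s).
#' @param valid logical per pixel.
#' @param smoothed has temporal smoothing been applied.
#' @return a `concentration_stack`.
#' @export
concentration_stack <- function(values, channel_idx, image_shape, timestamps,
                                valid, smoothed = FALSE) {
  structure(list(values = values, channel_idx = as.integer(channel_idx),
                 image_shape = as.integer(image_shape),
                 timestamps = as.numeric(timestamps),
                 valid = valid, smoothed = smoothed),
            class = "concentration_stack")
}

#' Moving-average smoothing over one heartbeat
#'
#' Centred moving average with window `w = round(frame_rate * 60 /
#' heart_rate)` frames (9 frames at 69 bpm and 10 Hz), the standard way to
#' remove pulsatility from a perfusion signal. Edges use shrinking windows so
#' the output length equals the input length.
#'
#' @param x numeric vector or (time x series) matrix, uniformly sampled.
#' @param heart_rate_bpm heart rate.
#' @param frame_rate_hz sampling rate.
#' @param window override the window length directly (frames).
#' @return smoothed object of the same shape.
#' @export
smooth_series <- function(x, heart_rate_bpm = 69, frame_rate_hz = 10,
                          window = NULL) {
  w <- if (!is.null(window)) as.integer(window)
       else as.integer(round(frame_rate_hz * 60 / heart_rate_bpm))
  mat <- is.matrix(x)
  X <- if (mat) x else matrix(x, ncol = 1)
  n <- nrow(X)
  if (w > n) stop("filter error: window longer than the series")
  if (w <= 1) return(x)
  h1 <- (w - 1L) %/% 2L; h2 <- w - 1L - h1
  nas <- colSums(is.na(X)) > 0
  if (any(nas)) X[, nas] <- 0
  # per-column cumulative sums without a per-column loop: cumsum the whole
  # column-major vector, then subtract each column's starting offset
  cs <- cumsum(as.vector(X))
  dim(cs) <- dim(X)
  offset <- c(0, cs[n, -ncol(X), drop = TRUE])
  cs <- sweep(cs, 2, offset)
  cs <- rbind(0, cs)
  i <- seq_len(n)
  lo <- pmax(i - h1, 1L); hi <- pmin(i + h2, n)
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  out[, nas] <- NA_real_
  if (mat) out else out[, 1]
}

#' Heartbeat smoothing window in frames
#'
#' @inheritParams smooth_series
#' @return integer window length.
#' @export
heartbeat_window <- function(heart_rate_bpm = 69, frame_rate_hz = 10) {
  as.integer(round(frame_rate_hz * 60 / heart_rate_bpm))
}

# per-pixel maximum of the heartbeat-smoothed series; the workhorse behind
# occlusivity/contact thresholds ("ever >= 20%?")
.pixel_smoothed_max <- function(conc, heart_rate_bpm, frame_rate_hz) {
  sm <- smooth_series(conc$values, heart_rate_bpm, frame_rate_hz)
  col_max_cpp(sm)
}
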