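# Shared fixtures, built once per test run. The default-resolution chip
# (15 um/px, 256 x 512) is what the acceptance checks use; unit tests mostly
# run on a coarser 30 um/px raster of the same chip for speed.

.fix <- new.env()

default_layout <- function() {
  if (is.null(.fix$layout)) .fix$layout <- build_symmetric_tree()
  .fix$layout
}

default_maps <- function() {
  if (is.null(.fix$maps)) .fix$maps <- rasterize_layout(default_layout())
  .fix$maps
}

coarse_layout <- function() {
  if (is.null(.fix$coarse)) {
    .fix$coarse <- build_symmetric_tree(pixel_scale = 30, image_shape = c(128L, 256L))
  }
  .fix$coarse
}

coarse_maps <- function() {
  if (is.null(.fix$coarse_maps)) .fix$coarse_maps <- rasterize_layout(coarse_layout())
  .fix$coarse_maps
}

# single wide straight channel: room for a full 16-px annulus inside the lumen
wide_channel_layout <- function(pixel_scale = 15) {
  seg <- list(id = 1L, order = 8L, diameter_um = 555, length_um = 3000,
              parent = NA_integer_, children = integer(0),
              centerline = rbind(c(400, 960), c(3400, 960)))
  chip_layout(list(seg), inlet_ids = 1L, pixel_scale = pixel_scale,
              image_shape = c(128L, 256L))
}

# short protocol used by unit tests (the full 180 s / 10 Hz timeline is
# exercised by the acceptance suite)
short_protocol <- function(case = "balloon", seed = 1L) {
  protocol_config(case = case, frame_rate_hz = 5, pre_roll_s = 4,
                  infusion_duration_s = 10, infusion_volume_ml = 5,
                  holding_s = 6, total_recording_s = 30,
                  heart_rate_bpm = 69, seed = seed)
}

# a cached small synthetic experiment (coarse raster, short protocol)
small_experiment <- function() {
  if (is.null(.fix$small_exp)) {
    lay <- coarse_layout(); maps <- coarse_maps()
    th <- place_microthrombi(lay, maps, n = 5, rng_seed = 11)
    .fix$small_exp <- list(
      layout = lay, maps = maps, thrombi = th,
      sim = run_protocol(lay, maps, th, short_protocol(seed = 11), noise = TRUE)
    )
  }
  .fix$small_exp
}

# synthetic concentration stack with a given per-pixel time course
make_conc_stack <- function(values, channel_idx, image_shape, timestamps) {
  concentration_stack(values, channel_idx, image_shape, timestamps,
                      valid = rep(TRUE, ncol(values)))
}

# most-central channel pixel (minimal radial offset, near mid-length)
central_channel_pixel <- function(maps) {
  idx <- which(maps$channel_mask)
  off <- maps$offset_um[idx]
  st <- maps$station_um[idx]
  score <- off + abs(st - stats::median(st)) / 1e3
  i <- idx[which.min(score)]
  c(row = ((i - 1) %% maps$image_shape[1]) + 1,
    col = ((i - 1) %/% maps$image_shape[1]) + 1,
    idx = i)
}

# brute-force Euclidean distance of every pixel to a footprint (ROI oracle)
brute_force_distance <- function(fp, image_shape) {
  rows <- image_shape[1]; cols <- image_shape[2]
  fr <- (fp - 1) %% rows; fc <- (fp - 1) %/% rows
  d <- matrix(Inf, rows, cols)
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    d[r, cc] <- sqrt(min((r - 1 - fr)^2 + (cc - 1 - fc)^2))
  }
  d
}
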