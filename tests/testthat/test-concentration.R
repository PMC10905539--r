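test_that("channel extraction matches the rasterized layout", {
  ex <- small_experiment()
  mask <- extract_channel_mask(ex$sim$frames, layout = ex$layout)
  expect_identical(mask, ex$maps$channel_mask)
})

test_that("threshold extraction recovers the channel area within 2%", {
  lay <- wide_channel_layout(); maps <- rasterize_layout(lay)
  op <- optics_config(noise_sd_frac = 0)
  grid <- build_transport_grid(lay)
  field <- structure(list(conc = matrix(0, 3, grid$n_cv),
                          times = c(-2, -1, 0), grid = grid),
                     class = "transport_field")
  fs <- render_frames(lay, maps, field, optics = op, noise = FALSE)
  # channels absorb nothing at c = 0: threshold extraction needs contrast, so
  # render a faint uniform dye level as the pre-infusion appearance
  field$conc[] <- 0.15
  fs <- render_frames(lay, maps, field, optics = op, noise = FALSE)
  fs$timestamps <- c(-2, -1, 0)
  mask <- extract_channel_mask(fs, layout = NULL, threshold_frac = 0.002)
  expect_lt(abs(sum(mask) - sum(maps$channel_mask)) / sum(maps$channel_mask), 0.02)
  # all-uniform frames cannot be segmented
  fs$values[] <- op$I0
  expect_error(extract_channel_mask(fs, layout = NULL), "extraction error")
})

test_that("per-pixel calibration inverts its own knots exactly and round-trips", {
  lay <- coarse_layout(); maps <- coarse_maps()
  op <- optics_config(noise_sd_frac = 0)
  cal <- render_calibration_frames(lay, maps, op, noise = FALSE, reps = 1)
  model <- fit_calibration(cal)
  expect_error(fit_calibration(cal, known_levels = 0.5), "config error|at least 2")
  # recovered level at each calibration frame equals the known level
  conc <- concentration_series(cal, model)
  for (k in seq_along(cal$levels)) {
    v <- conc$values[k, conc$valid]
    expect_equal(mean(abs(v - cal$levels[k])), 0, tolerance = 1e-9)
  }
  # round trip at an off-knot level: < 1% mean error at zero noise
  po <- mvochip:::.pixel_optics(lay, maps)
  I <- op$I0 * 10^(-(op$od_full * 0.3 * po$path_factor))
  fs <- frame_stack(matrix(round(I), 1, length(I), byrow = TRUE), po$channel_idx,
                    maps$image_shape, 0, maps$pixel_scale_um, op$I0)
  v <- concentration_series(fs, model)$values[1, ]
  expect_lt(mean(abs(v - 0.3), na.rm = TRUE), 0.01)
  # two levels {0, 1}: the optical-density midpoint (geometric mean of the
  # knot intensities) inverts to exactly 0.5
  iv <- matrix(c(1000, 500), 2, 1)
  m2 <- list(levels = c(0, 1), intensity = iv, valid = TRUE,
             channel_idx = 1L, image_shape = c(1L, 1L))
  class(m2) <- "calibration_model"
  fs2 <- frame_stack(matrix(sqrt(1000 * 500)), 1L, c(1L, 1L), 0, 15, 1000)
  expect_equal(concentration_series(fs2, m2)$values[1, 1], 0.5)
  # clamping: intensities beyond the c = 1 knot map to exactly 1
  fs3 <- frame_stack(matrix(200), 1L, c(1L, 1L), 0, 15, 1000)
  expect_equal(concentration_series(fs3, m2)$values[1, 1], 1)
})

test_that("calibration inversion is monotone on valid pixels", {
  lay <- coarse_layout(); maps <- coarse_maps()
  op <- optics_config()
  cal <- render_calibration_frames(lay, maps, op, noise = TRUE, reps = 3)
  model <- fit_calibration(cal)
  po <- mvochip:::.pixel_optics(lay, maps)
  cc <- seq(0, 1, by = 0.1)
  I <- op$I0 * 10^(-(op$od_full * outer(cc, po$path_factor)))
  fs <- frame_stack(round(I), po$channel_idx, maps$image_shape, seq_along(cc),
                    maps$pixel_scale_um, op$I0)
  v <- concentration_series(fs, model)$values
  dif <- apply(v[, model$valid], 2, diff)
  expect_true(all(dif > -1e-9))
})

test_that("heartbeat smoothing uses a 9-frame window and kills pulsatility", {
  expect_equal(heartbeat_window(69, 10), 9L)
  x <- rep(0.4, 200)
  expect_equal(smooth_series(x, 69, 10), x)
  # pure heartbeat-frequency sinusoid is attenuated below 5%
  f_hb <- 69 / 60; t <- (0:1799) / 10
  s <- sin(2 * pi * f_hb * t)
  sm <- smooth_series(s, 69, 10)
  inner <- 10:1790
  expect_lt(max(abs(sm[inner])) / max(abs(s)), 0.05)
  # integral preservation bound
  w <- 9; fr <- 10
  x2 <- cumsum(rnorm(300)) / 10
  d <- abs(sum(smooth_series(x2, 69, 10)) / fr - sum(x2) / fr)
  expect_lte(d, w * max(abs(x2)) / fr)
  expect_error(smooth_series(1:5, window = 9), "filter error")
})

test_that("generator-to-pipeline concentration error stays below 0.02", {
  ex <- small_experiment()
  sim <- ex$sim
  model <- fit_calibration(sim$calibration)
  conc <- concentration_series(sim$frames, model)
  po <- mvochip:::.pixel_optics(ex$layout, ex$maps)
  truth_px <- sim$field$conc[, mvochip:::.cv_index_vec(sim$field$grid, po$segment, po$station_um)]
  fp <- unlist(lapply(ex$thrombi, function(t) t$footprint))
  keep <- which(conc$valid & !(conc$channel_idx %in% fp))
  err <- mean(abs(conc$values[, keep] - truth_px[, keep]))
  expect_lt(err, 0.02)
})
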