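test_that("detection recovers every generated thrombus and nothing else", {
  ex <- small_experiment()
  sim <- ex$sim
  model <- fit_calibration(sim$calibration)
  det <- detect_thrombi(sim$frames, ex$maps$channel_mask, ex$maps, model)
  m <- match_detections(det, sim$truth)
  expect_equal(length(det), length(ex$thrombi))
  expect_true(all(!is.na(m$detection) & !is.na(m$truth)))
  expect_true(all(m$iou > 0.5))
  # a junction thrombus is flagged at_bifurcation with >= 2 segments
  for (i in seq_along(det)) {
    tr <- ex$thrombi[[m$truth[m$detection == i]]]
    expect_setequal(det[[i]]$occupied_segments, tr$occupied_segments)
    if (length(tr$occupied_segments) > 1) {
      expect_true(det[[i]]$at_bifurcation)
      expect_gte(det[[i]]$n_segments, 2)
    }
    expect_equal(det[[i]]$projected_area_mm2,
                 length(det[[i]]$footprint) * ex$maps$pixel_scale_um^2 * 1e-6)
  }
  # clean chip: no detections
  sim0 <- run_protocol(ex$layout, ex$maps, list(), short_protocol(seed = 2),
                       noise = TRUE, compute_truth = FALSE)
  det0 <- detect_thrombi(sim0$frames, ex$maps$channel_mask, ex$maps, model)
  expect_length(det0, 0)
})

test_that("annulus ROI has the printed geometry inside a wide channel", {
  lay <- wide_channel_layout(); maps <- rasterize_layout(lay)
  # single-pixel footprint at the channel centre
  centre <- central_channel_pixel(maps)
  fp <- unname(centre["idx"])
  roi <- build_roi(list(footprint = fp), maps$channel_mask, c(128L, 256L))
  d <- brute_force_distance(fp, c(128L, 256L))
  expect_setequal(roi$annulus, which(d > 5 & d <= 16 & maps$channel_mask))
  # radial width along the unobstructed row through the footprint: 11 px
  ann_img <- matrix(FALSE, 128, 256); ann_img[roi$annulus] <- TRUE
  row_run <- rle(ann_img[centre["row"], ])
  expect_equal(max(row_run$lengths[row_run$values]), 11)
  # 11 px at 15 um/px is the ca. 165 um annulus width
  expect_equal(11 * maps$pixel_scale_um, 165)
  # edge band is the immediate Euclidean neighbourhood, disjoint from both
  expect_setequal(roi$edge_band, which(d > 0 & d <= 1 & maps$channel_mask))
  expect_length(intersect(roi$annulus, fp), 0)
  expect_length(intersect(roi$edge_band, roi$annulus), 0)
})

test_that("dilation equals the distance-transform oracle on random footprints", {
  set.seed(42)
  shape <- c(48L, 48L)
  mask <- matrix(TRUE, shape[1], shape[2])
  for (k in 1:50) {
    seed_px <- sample.int(prod(shape), 1)
    fp <- unique(c(seed_px, seed_px + sample(c(-1, 1, -48, 48, -49, 47), 6)))
    fp <- fp[fp >= 1 & fp <= prod(shape)]
    roi <- build_roi(list(footprint = fp), mask, shape)
    d <- brute_force_distance(fp, shape)
    expect_setequal(roi$annulus, which(d > 5 & d <= 16))
    expect_setequal(roi$edge_band, which(d > 0 & d <= 1))
  }
})

test_that("corner clipping keeps ROI invariants; glass-only annuli are degenerate", {
  mask <- matrix(TRUE, 20L, 20L)
  roi <- build_roi(list(footprint = 1L), mask, c(20L, 20L))  # image corner
  expect_false(roi$degenerate)
  expect_length(intersect(roi$annulus, 1L), 0)
  # annulus entirely on glass -> degenerate, metrics missing
  glass <- matrix(FALSE, 20L, 20L); glass[1] <- TRUE
  roi2 <- build_roi(list(footprint = 1L), glass, c(20L, 20L))
  expect_true(roi2$degenerate)
  cs <- make_conc_stack(matrix(0.5, 3, 1), 1L, c(20L, 20L), 0:2)
  dm <- dose_metrics(roi2, cs)
  expect_true(dm$degenerate)
  expect_true(is.na(dm$c_max) && is.na(dm$D_final_s))
})

test_that("dose metrics reproduce closed-form integrals", {
  # a 2-px annulus observed over the full 180 s recording at 10 Hz
  idx <- c(5L, 6L)
  ts <- seq(-10, 169.9, by = 0.1)
  roi <- structure(list(annulus = idx, edge_band = integer(0),
                        footprint = 1L, degenerate = FALSE),
                   class = "annulus_roi")
  const <- make_conc_stack(matrix(0.5, length(ts), 2), idx, c(20L, 20L), ts)
  dm <- dose_metrics(roi, const, 10, 69)
  expect_equal(dm$c_max, 0.5)
  expect_equal(dm$D_final_s, 0.5 * 179.9, tolerance = 1e-9)
  zero <- make_conc_stack(matrix(0, length(ts), 2), idx, c(20L, 20L), ts)
  dm0 <- dose_metrics(roi, zero, 10, 69)
  expect_equal(dm0$c_max, 0)
  expect_equal(dm0$D_final_s, 0)
  # linear ramp 0 -> 1: integral 1/2 span, c_max ~ 1 (shrinking-window edges)
  ramp <- (ts - ts[1]) / (ts[length(ts)] - ts[1])
  dmr <- dose_metrics(roi, make_conc_stack(cbind(ramp, ramp), idx, c(20L, 20L), ts), 10, 69)
  expect_equal(dmr$D_final_s, 179.9 / 2, tolerance = 0.01 * 179.9 / 2)
  expect_equal(dmr$c_max, 1, tolerance = 0.01)
  # trapezoid cumulative integral against an independent summation oracle
  set.seed(7); noisy <- pmin(pmax(cumsum(rnorm(length(ts))) / 40 + 0.3, 0), 1)
  dmn <- dose_metrics(roi, make_conc_stack(cbind(noisy, noisy), idx, c(20L, 20L), ts), 10, 69)
  sm <- smooth_series(noisy, 69, 10)
  oracle <- 0
  for (i in 2:length(ts)) oracle <- oracle + (sm[i] + sm[i - 1]) / 2 * (ts[i] - ts[i - 1])
  expect_equal(dmn$D_final_s, oracle, tolerance = 1e-9)
})

test_that("occlusivity threshold semantics are strict", {
  lay <- coarse_layout(); maps <- coarse_maps()
  ch <- which(maps$channel_mask)
  # segment 2's distal subtree is segments 4,5,8..11
  distal <- c(4L, 5L, 8:11)
  px_dist <- which(maps$segment_labels[ch] %in% distal)
  pixel_max <- rep(0.05, length(ch))
  expect_true(classify_segment_occlusivity(2L, pixel_max, ch, maps, lay))
  # a single distal pixel reaching exactly the threshold stays occlusive
  # only under strict less-than if it is BELOW; == 0.20 flips to nonocclusive
  pixel_max[px_dist[1]] <- 0.2
  expect_false(classify_segment_occlusivity(2L, pixel_max, ch, maps, lay))
  pixel_max[px_dist[1]] <- 0.2 - 1e-9
  expect_true(classify_segment_occlusivity(2L, pixel_max, ch, maps, lay))
  # leaf rule: pixels of the leaf distal to the footprint decide
  leaf <- 8L
  leaf_px <- which(maps$segment_labels[ch] == leaf)
  st <- maps$station_um[ch[leaf_px]]
  fp <- ch[leaf_px[st < 200]]
  pm2 <- rep(0, length(ch))
  expect_true(classify_segment_occlusivity(leaf, pm2, ch, maps, lay, footprint = fp))
  pm2[leaf_px[which.max(st)]] <- 0.9
  expect_false(classify_segment_occlusivity(leaf, pm2, ch, maps, lay, footprint = fp))
})

test_that("thrombus aggregation and contact taxonomy follow their definitions", {
  expect_equal(classify_thrombus(c(TRUE, TRUE)), "fully_occlusive")
  expect_equal(classify_thrombus(c(TRUE, FALSE)), "semiocclusive")
  expect_equal(classify_thrombus(c(FALSE, FALSE)), "nonocclusive")
  expect_true(classify_thrombus(TRUE) != "semiocclusive")
  expect_true(classify_thrombus(FALSE) != "semiocclusive")
  expect_error(classify_thrombus(logical(0)))

  roi <- structure(list(annulus = 2:3, edge_band = 4L, degenerate = FALSE),
                   class = "annulus_roi")
  idx <- 1:4
  mx <- c(0, 0.1, 0.1, 0.3)
  expect_equal(classify_contact(roi, mx, idx), "contact")
  mx <- c(0, 0.25, 0.1, 0.1)
  expect_equal(classify_contact(roi, mx, idx), "diffusion_range")
  mx <- c(0, 0.19, 0.19, 0.19)
  expect_equal(classify_contact(roi, mx, idx), "no_contact")
  # non-strict >= at the threshold itself
  mx <- c(0, 0.1, 0.1, 0.2)
  expect_equal(classify_contact(roi, mx, idx), "contact")
  roi$degenerate <- TRUE
  expect_equal(classify_contact(roi, mx, idx), "no_contact")
})

test_that("size/location tables count the cohort correctly", {
  ex <- small_experiment()
  sim <- ex$sim
  model <- fit_calibration(sim$calibration)
  det <- detect_thrombi(sim$frames, ex$maps$channel_mask, ex$maps, model)
  cats <- categorize_size_location(det, ex$layout, ex$maps$image_shape)
  expect_equal(sum(cats$n_segments_hist),  length(det))
  expect_equal(sum(cats$heatmap), sum(lengths(lapply(det, `[[`, "footprint"))))
  expect_equal(unname(cats$order_segment_counts["5"] + cats$order_segment_counts["6"] +
                 cats$order_segment_counts["7"] + cats$order_segment_counts["8"]),
               sum(vapply(det, function(d) d$n_segments, 0L)))
  one <- det[[which.max(vapply(det, function(d) d$n_segments, 0L))]]
  h <- categorize_size_location(list(one), ex$layout, ex$maps$image_shape)
  expect_equal(unname(h$n_segments_hist[as.character(one$n_segments)]), 1)
  expect_error(categorize_size_location(list(), ex$layout))
})
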