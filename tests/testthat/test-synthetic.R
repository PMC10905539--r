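test_that("placement is deterministic, well-formed and respects the mask", {
  lay <- coarse_layout(); maps <- coarse_maps()
  expect_length(place_microthrombi(lay, maps, n = 0, rng_seed = 1), 0)
  th <- place_microthrombi(lay, maps, n = 6, rng_seed = 3)
  th2 <- place_microthrombi(lay, maps, n = 6, rng_seed = 3)
  expect_identical(th, th2)
  ch <- which(maps$channel_mask)
  for (t in th) {
    expect_true(all(t$footprint %in% ch))
    expect_setequal(t$occupied_segments,
                    unique(maps$segment_labels[t$footprint]))
    expect_gte(length(t$occupied_segments), 1)
    expect_lte(length(t$occupied_segments), 5)
    # ground truth aggregation rule is self-consistent
    expect_equal(t$occlusivity_class, aggregate_occlusivity(t$per_segment_occlusive))
  }
})

test_that("bifurcation affinity 1 makes every thrombus span >= 2 segments", {
  lay <- coarse_layout(); maps <- coarse_maps()
  pooled <- unlist(lapply(1:40, function(s) {
    th <- place_microthrombi(lay, maps, n = 5, rng_seed = s,
                             bifurcation_affinity = 1,
                             occlusivity_probs = c(0.5, 0, 0.5))
    vapply(th, function(t) length(t$occupied_segments), 0L)
  }))
  expect_gte(length(pooled), 200)
  expect_true(all(pooled >= 2))
})

test_that("occlusivity constraints respect thrombus geometry", {
  lay <- coarse_layout(); maps <- coarse_maps()
  tab <- segment_table(lay)
  for (s in 1:10) {
    th <- place_microthrombi(lay, maps, n = 6, rng_seed = s)
    for (t in th) {
      d <- tab$diameter_um[match(t$occupied_segments, tab$id)]
      # only channels no wider than the thrombus can be occluded
      expect_true(all(d[t$per_segment_occlusive] <= t$nominal_size))
      if (t$occlusivity_class == "semiocclusive")
        expect_gte(length(t$occupied_segments), 2)
    }
  }
  # geometry mode: occlusive iff the footprint covers the channel width
  th <- place_microthrombi(lay, maps, n = 6, rng_seed = 2, occlusivity = "geometry")
  for (t in th) {
    d <- tab$diameter_um[match(t$occupied_segments, tab$id)]
    expect_equal(unname(t$per_segment_occlusive), unname(t$nominal_size >= d))
  }
})

test_that("shadowing is detected from occlusion topology", {
  lay <- default_layout()
  mt <- function(occ, flags) {
    structure(list(occupied_segments = occ, per_segment_occlusive = flags),
              class = "microthrombus")
  }
  # A occludes the order-7 segment 2; B sits in its subtree; C in segment 3's
  a <- mt(2L, TRUE)
  b <- mt(8L, FALSE)       # leaf under 4, under 2 -> shadowed by A
  c_ <- mt(12L, FALSE)     # leaf under 6, under 3 -> unshadowed
  expect_equal(shadowed_thrombi(lay, list(a, b, c_)), c(FALSE, TRUE, FALSE))
  # a thrombus straddling both branches is only shadowed if all are blocked
  d <- mt(c(4L, 5L), c(FALSE, FALSE))
  expect_equal(shadowed_thrombi(lay, list(a, d))[2], TRUE)
  e <- mt(c(4L, 12L), c(FALSE, FALSE))   # one foot outside A's subtree
  expect_equal(shadowed_thrombi(lay, list(a, e))[2], FALSE)
  expect_false(any(shadowed_thrombi(lay, list(b, c_))))
})

test_that("protocol configs validate their timeline", {
  p <- protocol_config("balloon")
  expect_equal(p$q_inf_ml_min, 30)
  expect_equal(round(p$total_recording_s * p$frame_rate_hz), 1800)
  expect_error(protocol_config("balloon", total_recording_s = 20), "cover")
})

test_that("a synthetic run renders the protocol timeline with ground truth", {
  ex <- small_experiment()
  sim <- ex$sim; proto <- sim$protocol
  fs <- sim$frames
  expect_equal(length(fs$timestamps), round(proto$total_recording_s * proto$frame_rate_hz))
  expect_equal(fs$timestamps[1], -proto$pre_roll_s)
  expect_equal(unique(round(diff(fs$timestamps), 9)), 1 / proto$frame_rate_hz)
  # pre-roll frames carry no dye: channel pixels at clean-chip intensity
  pre <- which(fs$timestamps < 0)
  i0 <- which.min(sim$calibration$levels)
  clean <- sim$calibration$values[i0, ]
  fp <- unlist(lapply(ex$thrombi, function(t) t$footprint))
  keep <- !(fs$channel_idx %in% fp)
  dev <- abs(colMeans(fs$values[pre, keep, drop = FALSE]) - clean[keep]) / clean[keep]
  expect_lt(max(dev), 0.05)
  # ground truth layers agree with the generator's thrombi
  expect_equal(sim$truth$true_thrombus_occlusivity,
               vapply(ex$thrombi, function(t) aggregate_occlusivity(t$per_segment_occlusive), ""))
  expect_equal(nrow(sim$truth$effective$table), length(ex$thrombi))
})

test_that("paired cases share the thrombus configuration and differ only at the inlet", {
  lay <- coarse_layout(); maps <- coarse_maps()
  th <- place_microthrombi(lay, maps, n = 4, rng_seed = 5)
  sb <- run_protocol(lay, maps, th, short_protocol("balloon", seed = 5),
                     noise = FALSE, compute_truth = FALSE)
  sn <- run_protocol(lay, maps, th, short_protocol("no_balloon", seed = 5),
                     noise = FALSE, compute_truth = FALSE)
  expect_identical(lapply(sb$truth$thrombi, `[[`, "footprint"),
                   lapply(sn$truth$thrombi, `[[`, "footprint"))
  expect_identical(sb$truth$true_thrombus_occlusivity,
                   sn$truth$true_thrombus_occlusivity)
  # pre-roll is identical; the infusion phase differs
  pre <- which(sb$frames$timestamps < 0)
  expect_equal(sb$frames$values[pre, ], sn$frames$values[pre, ])
  inf <- which(sb$frames$timestamps > 2 & sb$frames$timestamps < 8)
  expect_false(isTRUE(all.equal(sb$frames$values[inf, ], sn$frames$values[inf, ])))
})

test_that("rendering follows Beer-Lambert attenuation", {
  lay <- wide_channel_layout(); maps <- rasterize_layout(lay)
  op <- optics_config(noise_sd_frac = 0)
  po <- mvochip:::.pixel_optics(lay, maps)
  grid <- build_transport_grid(lay)
  field <- structure(list(conc = matrix(0.25, 2, grid$n_cv),
                          times = c(0, 1), grid = grid),
                     class = "transport_field")
  fs <- render_frames(lay, maps, field, optics = op, noise = FALSE)
  # zero concentration -> background intensity on every channel pixel
  field0 <- field; field0$conc[] <- 0
  fs0 <- render_frames(lay, maps, field0, optics = op, noise = FALSE)
  expect_true(all(fs0$values == op$I0))
  # doubling c doubles the optical density (before quantization noise)
  field2 <- field; field2$conc[] <- 0.5
  fs2 <- render_frames(lay, maps, field2, optics = op, noise = FALSE)
  mid <- which.max(po$path_factor)
  od1 <- -log10(fs$values[1, mid] / op$I0)
  od2 <- -log10(fs2$values[1, mid] / op$I0)
  expect_equal(od2 / od1, 2, tolerance = 1e-2)
})

test_that("ground truth JSON serializes", {
  ex <- small_experiment()
  path <- tempfile(fileext = ".json")
  write_ground_truth(ex$sim$truth, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$format, "mvochip-truth/1")
  expect_equal(length(obj$thrombi$id), length(ex$thrombi))
})
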