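#' Detect microthrombi from pre-infusion frames
#'
#' Channel pixels whose mean pre-infusion intensity deviates from the
#' clean-chip reference by more than `threshold` (fraction of the reference)
#' are thrombus candidates; 8-connected components of at least `min_area`
#' pixels are kept. Occupied segments and orders come from the segment label
#' map; a thrombus is `at_bifurcation` when its footprint comes within 2 px
#' of a junction point.
#'
#' @param frames a `frame_stack` with pre-infusion frames (timestamps < 0).
#' @param mask logical channel mask.
#' @param maps `segment_maps` (labels, junctions).
#' @param clean_reference per-pixel clean-chip intensities: either a numeric
#'   vector aligned with `frames$channel_idx` or a `calibration_model`
#'   (its level-0 knots are used).
#' @param pixel_scale_um um per pixel.
#' @param threshold relative deviation flagging a thrombus pixel.
#' @param min_area minimum footprint size, px.
#' @return list of `thrombus_detection`: id, footprint (linear indices),
#'   centroid, projected_area_mm2, occupied_segments, orders, n_segments,
#'   at_bifurcation.
#' @export
detect_thrombi <- function(frames, mask, maps, clean_reference,
                           pixel_scale_um = frames$pixel_scale_um,
                           threshold = 0.3, min_area = 4) {
  pre <- which(frames$timestamps < 0)
  if (!length(pre)) stop("detection error: no pre-infusion frames")
  if (inherits(clean_reference, "calibration_model")) {
    i0 <- which.min(clean_reference$levels)
    ref <- clean_reference$intensity[i0, match(frames$channel_idx,
                                               clean_reference$channel_idx)]
  } else ref <- clean_reference
  mean_pre <- colMeans(frames$values[pre, , drop = FALSE])
  in_mask <- frames$channel_idx %in% which(mask)
  cand <- which(in_mask & abs(mean_pre - ref) / pmax(ref, 1) > threshold)
  if (!length(cand)) return(list())
  rows <- frames$image_shape[1]
  idx <- frames$channel_idx[cand]
  prow <- ((idx - 1) %% rows) + 1L
  pcol <- ((idx - 1) %/% rows) + 1L
  comp <- label8_cpp(prow, pcol, rows)
  keep <- which(tabulate(comp) >= min_area)
  bif <- maps$bifurcation_px
  out <- list()
  for (k in seq_along(keep)) {
    sel <- comp == keep[k]
    fp <- idx[sel]
    segs <- sort(unique(maps$segment_labels[fp]))
    segs <- segs[segs > 0]
    cr <- mean(prow[sel]); cc <- mean(pcol[sel])
    near_bif <- FALSE
    if (nrow(bif)) {
      d2 <- outer(prow[sel] - 1L, bif$row, "-")^2 + outer(pcol[sel] - 1L, bif$col, "-")^2
      near_bif <- min(d2) <= 4
    }
    out[[k]] <- structure(list(
      id = k, footprint = fp, centroid = c(row = cr, col = cc),
      projected_area_mm2 = length(fp) * pixel_scale_um^2 * 1e-6,
      occupied_segments = segs,
      n_segments = length(segs),
      at_bifurcation = near_bif), class = "thrombus_detection")
  }
  out
}

#' Annulus region of interest around a thrombus
#'
#' The footprint is enlarged in all directions by `outer_px` (Euclidean
#' dilation, 16 px = ca. 240 um at 15 um/px - the diffusion length of the
#' balloon-holding minute); the footprint enlarged by `gap_px` (5 px = ca.
#' 75 um, guarding against small thrombus movements) is removed, leaving an
#' annulus of width 11 px (ca. 165 um) along any unobstructed direction.
#' Both are intersected with the channel mask: glass carries no dye. The
#' edge band is the 1-px Euclidean neighbourhood of the footprint, used for
#' the contact criterion. Other thrombi's footprints are excluded.
#'
#' @param detection a `thrombus_detection` (or anything with a `footprint`).
#' @param mask logical channel mask.
#' @param image_shape integer (rows, cols).
#' @param other_footprints linear indices of all other thrombus pixels.
#' @param outer_px,gap_px annulus radii in px.
#' @return an `annulus_roi`: `annulus`, `edge_band` (linear indices),
#'   `degenerate` flag.
#' @export
build_roi <- function(detection, mask, image_shape,
                      other_footprints = integer(0),
                      outer_px = 16, gap_px = 5) {
  fp <- if (is.list(detection)) detection$footprint else detection
  if (!length(fp)) stop("footprint is empty")
  rows <- image_shape[1]; cols <- image_shape[2]
  src <- matrix(1L, rows, cols)
  src[fp] <- 0L
  d <- EBImage::distmap(src, metric = "euclidean")
  d <- d@.Data
  keep <- mask
  if (length(other_footprints)) keep[other_footprints] <- FALSE
  annulus <- which(d > gap_px & d <= outer_px & keep)
  edge <- which(d > 0 & d <= 1 & keep)
  structure(list(annulus = annulus, edge_band = edge,
                 footprint = fp, outer_px = outer_px, gap_px = gap_px,
                 degenerate = length(annulus) == 0),
            class = "annulus_roi")
}

#' Dose metrics of an ROI
#'
#' The ROI concentration `c(t)` is the heartbeat-smoothed mean over the
#' annulus pixels per frame; the cumulated dose `D(t)` is its running
#' trapezoidal time integral (units: seconds of full-strength exposure).
#' `c_max = max_t c(t)`; `D_final` is `D` at the last recorded frame (the
#' 180 s mark of the recording).
#'
#' @param roi an `annulus_roi`.
#' @param conc a `concentration_stack` covering the full recording.
#' @param frame_rate_hz,heart_rate_bpm smoothing parameters.
#' @return a `dose_metrics`: `c_t`, `D_t`, `c_max`, `D_final_s`,
#'   `timestamps`; all NA when the ROI is degenerate.
#' @export
dose_metrics <- function(roi, conc, frame_rate_hz = 10, heart_rate_bpm = 69) {
  if (roi$degenerate)
    return(structure(list(c_t = NULL, D_t = NULL, c_max = NA_real_,
                          D_final_s = NA_real_, degenerate = TRUE),
                     class = "dose_metrics"))
  cols <- match(roi$annulus, conc$channel_idx)
  cols <- cols[!is.na(cols)]
  cols <- cols[conc$valid[cols]]
  if (!length(cols))
    return(structure(list(c_t = NULL, D_t = NULL, c_max = NA_real_,
                          D_final_s = NA_real_, degenerate = TRUE),
                     class = "dose_metrics"))
  c_raw <- rowMeans(conc$values[, cols, drop = FALSE], na.rm = TRUE)
  c_t <- smooth_series(c_raw, heart_rate_bpm, frame_rate_hz)
  tt <- conc$timestamps
  D_t <- c(0, cumsum((head(c_t, -1) + tail(c_t, -1)) / 2 * diff(tt)))
  structure(list(c_t = c_t, D_t = D_t, timestamps = tt,
                 c_max = max(c_t), D_final_s = D_t[length(D_t)],
                 degenerate = FALSE),
            class = "dose_metrics")
}

#' Classify the occlusivity of one thrombus segment
#'
#' A thrombus segment is occlusive when every pixel of every segment distal
#' to it keeps a smoothed dye concentration strictly below the threshold at
#' all times; otherwise it is nonocclusive. For a leaf (empty distal
#' subtree) the pixels of the leaf itself distal to the footprint along the
#' centerline are used. Pixels belonging to any thrombus footprint or to
#' invalid calibration pixels are excluded; an empty pixel set classifies as
#' occlusive (nothing distal was ever reached).
#'
#' @param segment_id the thrombus segment.
#' @param pixel_max per-pixel maxima of the smoothed concentration, aligned
#'   with `conc_channel_idx` (see [pixel_smoothed_max]).
#' @param conc_channel_idx linear indices of those pixels.
#' @param maps `segment_maps`.
#' @param layout `chip_layout`.
#' @param footprint the thrombus's own footprint (for the leaf rule).
#' @param exclude_px pixels to ignore (all thrombus footprints).
#' @param threshold concentration threshold (default 0.20).
#' @param include_own_distal also include the thrombus-bearing segment's
#'   pixels distal to the footprint for non-leaf segments (default FALSE).
#' @return TRUE if occlusive.
#' @export
classify_segment_occlusivity <- function(segment_id, pixel_max,
                                         conc_channel_idx, maps, layout,
                                         footprint = integer(0),
                                         exclude_px = integer(0),
                                         threshold = 0.2,
                                         include_own_distal = FALSE) {
  distal <- distal_subtree(layout, segment_id)
  labels_px <- maps$segment_labels[conc_channel_idx]
  px <- integer(0)
  if (length(distal)) {
    px <- which(labels_px %in% distal)
    if (include_own_distal) px <- union(px, .own_distal_px(segment_id, maps,
                                                          conc_channel_idx,
                                                          footprint))
  } else {
    px <- .own_distal_px(segment_id, maps, conc_channel_idx, footprint)
  }
  if (length(exclude_px))
    px <- px[!(conc_channel_idx[px] %in% exclude_px)]
  vals <- pixel_max[px]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(TRUE)
  all(vals < threshold)
}

.own_distal_px <- function(segment_id, maps, conc_channel_idx, footprint) {
  labels_px <- maps$segment_labels[conc_channel_idx]
  st_px <- maps$station_um[conc_channel_idx]
  fp_same <- footprint[maps$segment_labels[footprint] == segment_id]
  st_max <- if (length(fp_same)) max(maps$station_um[fp_same]) else -Inf
  which(labels_px == segment_id & st_px > st_max)
}

#' Aggregate per-segment flags into the thrombus occlusivity class
#'
#' @param flags logical per-segment occlusivity flags.
#' @return "nonocclusive", "semiocclusive" or "fully_occlusive".
#' @export
classify_thrombus <- function(flags) aggregate_occlusivity(flags)

#' Classify drug contact of a thrombus
#'
#' Contact when any edge-band pixel's smoothed concentration reaches the
#' threshold (non-strict) at any time; otherwise diffusion range when any
#' annulus pixel reaches it; otherwise no contact. A degenerate ROI reports
#' no contact with the degenerate flag set.
#'
#' @param roi an `annulus_roi`.
#' @param pixel_max per-pixel smoothed maxima.
#' @param conc_channel_idx their pixel indices.
#' @param threshold contact threshold (default 0.20).
#' @return "contact", "diffusion_range" or "no_contact".
#' @export
classify_contact <- function(roi, pixel_max, conc_channel_idx, threshold = 0.2) {
  if (roi$degenerate) return("no_contact")
  mx <- function(pixels) {
    v <- pixel_max[match(pixels, conc_channel_idx)]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else -Inf
  }
  if (mx(roi$edge_band) >= threshold) return("contact")
  if (mx(roi$annulus) >= threshold) return("diffusion_range")
  "no_contact"
}

#' Per-pixel maxima of the heartbeat-smoothed concentration
#'
#' @param conc a `concentration_stack`.
#' @param heart_rate_bpm,frame_rate_hz smoothing parameters.
#' @return numeric vector aligned with `conc$channel_idx` (NA where invalid).
#' @export
pixel_smoothed_max <- function(conc, heart_rate_bpm = 69, frame_rate_hz = 10) {
  .pixel_smoothed_max(conc, heart_rate_bpm, frame_rate_hz)
}

#' Classify a cohort of thrombi from a concentration stack
#'
#' Shared classification core: builds ROIs, computes dose metrics and
#' classifies occlusivity and contact for every thrombus, excluding all
#' thrombus footprints from every pixel statistic. Used both by the
#' frames-based analysis and by the generator's field-oracle truth.
#'
#' @param conc a `concentration_stack`.
#' @param footprints list of footprint pixel index vectors.
#' @param occupied list of occupied-segment id vectors.
#' @param maps,layout chip geometry.
#' @param frame_rate_hz,heart_rate_bpm smoothing parameters.
#' @param threshold classification threshold.
#' @return list with `table` (one row per thrombus: occlusivity, contact,
#'   c_max, D_final_s, n_segments, ...) and `segment_flags` (list of logical
#'   vectors).
#' @export
classify_cohort <- function(conc, footprints, occupied, maps, layout,
                            frame_rate_hz = 10, heart_rate_bpm = 69,
                            threshold = 0.2) {
  mask <- matrix(FALSE, maps$image_shape[1], maps$image_shape[2])
  mask[conc$channel_idx] <- TRUE
  pmax_px <- .pixel_smoothed_max(conc, heart_rate_bpm, frame_rate_hz)
  all_fp <- unlist(footprints)
  tab <- segment_table(layout)
  n <- length(footprints)
  seg_flags <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fp <- footprints[[i]]
    others <- setdiff(all_fp, fp)
    roi <- build_roi(list(footprint = fp), mask, maps$image_shape,
                     other_footprints = others)
    dm <- dose_metrics(roi, conc, frame_rate_hz, heart_rate_bpm)
    segs <- occupied[[i]]
    flags <- vapply(segs, function(s)
      classify_segment_occlusivity(s, pmax_px, conc$channel_idx, maps, layout,
                                   footprint = fp, exclude_px = all_fp,
                                   threshold = threshold), TRUE)
    seg_flags[[i]] <- stats::setNames(flags, segs)
    rows[[i]] <- data.frame(
      id = i,
      n_segments = length(segs),
      orders = paste(sort(tab$order[match(segs, tab$id)]), collapse = "+"),
      occlusivity = classify_thrombus(flags),
      contact = classify_contact(roi, pmax_px, conc$channel_idx, threshold),
      c_max = dm$c_max, D_final_s = dm$D_final_s,
      degenerate_roi = dm$degenerate)
  }
  list(table = do.call(rbind, rows), segment_flags = seg_flags)
}

#' Size and location statistics of a detection cohort
#'
#' @param detections list of `thrombus_detection` (possibly pooled across
#'   experiments).
#' @param layout a `chip_layout`.
#' @param image_shape raster shape for the occurrence heatmap.
#' @return list: `n_segments_hist` (counts for 1..5 occupied segments),
#'   `order_segment_counts` (thrombus segments per vessel order),
#'   `same_order_counts` (thrombi with >= k same-order segments),
#'   `area_summary` (mean, quartiles of projected area),
#'   `heatmap` (per-pixel footprint occurrence counts).
#' @export
categorize_size_location <- function(detections, layout,
                                     image_shape = layout$image_shape) {
  if (!length(detections)) stop("at least one detection is required")
  tab <- segment_table(layout)
  nseg <- vapply(detections, function(d) d$n_segments, 0L)
  hist5 <- tabulate(pmin(nseg, 5L), 5L)
  names(hist5) <- as.character(1:5)
  ords <- unlist(lapply(detections, function(d) tab$order[match(d$occupied_segments, tab$id)]))
  order_counts <- table(factor(ords, levels = sort(unique(tab$order))))
  same_order <- sapply(1:5, function(k)
    sum(vapply(detections, function(d) {
      oc <- table(tab$order[match(d$occupied_segments, tab$id)])
      any(oc >= k)
    }, TRUE)))
  names(same_order) <- paste0(">=", 1:5)
  areas <- vapply(detections, function(d) d$projected_area_mm2, 0)
  heat <- matrix(0L, image_shape[1], image_shape[2])
  for (d in detections) heat[d$footprint] <- heat[d$footprint] + 1L
  list(n_segments_hist = hist5,
       order_segment_counts = order_counts,
       same_order_counts = same_order,
       area_summary = c(mean = mean(areas),
                        quantile(areas, c(0.25, 0.5, 0.75), type = 7)),
       heatmap = heat)
}
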