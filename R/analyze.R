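#' Analyze one recorded experiment end to end
#'
#' Full measurement pipeline: channel extraction, per-pixel calibration,
#' thrombus detection against the clean-chip reference, calibration
#' inversion, heartbeat smoothing, annulus ROIs, dose metrics and
#' occlusivity/contact classification.
#'
#' @param frames a `frame_stack` of the experiment.
#' @param calibration a `frame_stack` of uniform-level calibration frames
#'   (with a `levels` field).
#' @param layout the `chip_layout`; the mask is its rasterization.
#' @param maps optional precomputed `segment_maps`.
#' @param frame_rate_hz,heart_rate_bpm protocol timing.
#' @param threshold classification threshold (0.20).
#' @param detection_threshold,detection_min_area thrombus detection
#'   parameters.
#' @return an `experiment_analysis`: `table` (one row per detected
#'   thrombus), `detections`, `segment_flags`, `conc` (the concentration
#'   stack), `model` (calibration).
#' @export
analyze_experiment <- function(frames, calibration, layout, maps = NULL,
                               frame_rate_hz = 10, heart_rate_bpm = 69,
                               threshold = 0.2,
                               detection_threshold = 0.3,
                               detection_min_area = 4) {
  if (is.null(maps)) maps <- rasterize_layout(layout)
  mask <- maps$channel_mask
  model <- fit_calibration(calibration, mask = mask)
  detections <- detect_thrombi(frames, mask, maps, model,
                               threshold = detection_threshold,
                               min_area = detection_min_area)
  conc <- concentration_series(frames, model, mask = mask)
  res <- classify_cohort(conc,
                         lapply(detections, function(d) d$footprint),
                         lapply(detections, function(d) d$occupied_segments),
                         maps, layout,
                         frame_rate_hz = frame_rate_hz,
                         heart_rate_bpm = heart_rate_bpm,
                         threshold = threshold)
  tab <- res$table
  if (!is.null(tab) && nrow(tab)) {
    tab$projected_area_mm2 <- vapply(detections, function(d) d$projected_area_mm2, 0)
    tab$at_bifurcation <- vapply(detections, function(d) d$at_bifurcation, TRUE)
  }
  structure(list(table = tab, detections = detections,
                 segment_flags = res$segment_flags,
                 conc = conc, model = model, maps = maps),
            class = "experiment_analysis")
}

#' Match detections against ground truth by footprint overlap
#'
#' @param detections list of `thrombus_detection`.
#' @param truth a `ground_truth`.
#' @param min_iou intersection-over-union acceptance threshold.
#' @return data.frame: detection id, truth id (NA = spurious detection),
#'   iou; truth thrombi without a match appear with detection NA.
#' @export
match_detections <- function(detections, truth, min_iou = 0.5) {
  nd <- length(detections); nt <- length(truth$thrombi)
  rows <- list()
  used_t <- rep(FALSE, nt)
  for (i in seq_len(nd)) {
    fp <- detections[[i]]$footprint
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nt)) {
      tfp <- truth$thrombi[[j]]$footprint
      iou <- length(intersect(fp, tfp)) / length(union(fp, tfp))
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (!is.na(best_j) && best >= min_iou) used_t[best_j] <- TRUE
    rows[[i]] <- data.frame(detection = i,
                            truth = if (!is.na(best_j) && best >= min_iou) best_j else NA_integer_,
                            iou = best)
  }
  for (j in which(!used_t))
    rows[[length(rows) + 1]] <- data.frame(detection = NA_integer_, truth = j, iou = 0)
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(detection = integer(0), truth = integer(0), iou = numeric(0))
  out
}

#' Score pipeline classifications against the generator's field-oracle truth
#'
#' Matches detections to ground-truth thrombi and compares occlusivity and
#' contact labels against the effective (true-field) classification.
#'
#' @param analysis an `experiment_analysis`.
#' @param truth a `ground_truth` with an `effective` layer.
#' @return data.frame per matched thrombus: pipeline and truth labels plus
#'   agreement flags.
#' @export
score_classification <- function(analysis, truth) {
  if (is.null(truth$effective)) stop("ground truth has no effective layer")
  m <- match_detections(analysis$detections, truth)
  m <- m[!is.na(m$detection) & !is.na(m$truth), , drop = FALSE]
  if (!nrow(m)) return(data.frame())
  pt <- analysis$table[m$detection, ]
  et <- truth$effective$table[m$truth, ]
  data.frame(truth_id = m$truth, detection_id = m$detection, iou = m$iou,
             occlusivity = pt$occlusivity, occlusivity_truth = et$occlusivity,
             contact = pt$contact, contact_truth = et$contact,
             occlusivity_match = pt$occlusivity == et$occlusivity,
             contact_match = pt$contact == et$contact,
             mechanical_class = truth$true_thrombus_occlusivity[m$truth])
}
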