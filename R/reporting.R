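#' Cohort summary of dose metrics
#'
#' Quartiles (linear interpolation between order statistics, the common
#' spreadsheet convention) and arithmetic means of `c_max` and `D_final`
#' per experimental setting.
#'
#' @param metrics data.frame with columns `setting`, `c_max`, `D_final_s`.
#' @return data.frame: setting, metric, q1, median, q3, mean, n.
#' @export
summarize_cohort <- function(metrics) {
  stopifnot(all(c("setting", "c_max", "D_final_s") %in% names(metrics)))
  out <- list()
  for (s in unique(metrics$setting)) {
    sub <- metrics[metrics$setting == s, ]
    for (m in c("c_max", "D_final_s")) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (!length(v)) {
        warning("no values for setting ", s, ", metric ", m, "; row omitted")
        next
      }
      q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1]] <- data.frame(setting = s, metric = m,
                                           q1 = q[1], median = q[2], q3 = q[3],
                                           mean = mean(v), n = length(v))
    }
  }
  do.call(rbind, out)
}

#' Percent change and ratio between two settings
#'
#' `percent = 100 (treatment - reference) / reference`; `ratio =
#' treatment / reference`. The rounded percent uses half-away-from-zero
#' rounding (so 57.5 prints as 58 at integer precision).
#'
#' @param reference,treatment the two values (reference nonzero).
#' @return list: percent, ratio, percent_rounded.
#' @export
percent_change <- function(reference, treatment) {
  if (is.na(reference) || reference == 0)
    return(list(percent = NA_real_, ratio = NA_real_, percent_rounded = NA_real_))
  pct <- 100 * (treatment - reference) / reference
  list(percent = pct, ratio = treatment / reference,
       percent_rounded = sign(pct) * floor(abs(pct) + 0.5))
}

#' Contact and occlusivity fraction tables per case
#'
#' @param classifications data.frame with `case`, `occlusivity`, `contact`.
#' @param segment_flags optional data.frame with `case`, `order`,
#'   `occlusive` for the per-order occlusive-segment fractions.
#' @return list of fraction tables (each row sums to 1).
#' @export
fraction_tables <- function(classifications, segment_flags = NULL) {
  stopifnot(nrow(classifications) >= 1)
  frac <- function(x, levels) {
    t <- table(factor(x, levels = levels))
    as.data.frame(t(as.matrix(t / sum(t))))
  }
  occ_lv <- c("nonocclusive", "semiocclusive", "fully_occlusive")
  con_lv <- c("contact", "diffusion_range", "no_contact")
  out <- list(occlusivity = NULL, contact = NULL)
  for (cs in unique(classifications$case)) {
    sub <- classifications[classifications$case == cs, ]
    o <- cbind(case = cs, frac(sub$occlusivity, occ_lv))
    k <- cbind(case = cs, frac(sub$contact, con_lv))
    out$occlusivity <- rbind(out$occlusivity, o)
    out$contact <- rbind(out$contact, k)
  }
  if (!is.null(segment_flags)) {
    ag <- stats::aggregate(occlusive ~ case + order, data = segment_flags, FUN = mean)
    names(ag)[names(ag) == "occlusive"] <- "occlusive_fraction"
    out$per_order_occlusive <- ag
  }
  out
}

#' Compare two settings of a paired cohort
#'
#' The bench design pairs every thrombus configuration across settings
#' (same seed, same thrombi). When the metrics table carries `seed` and
#' `truth_id` columns, the comparison refuses to run unless every ROI of
#' the reference setting has its counterpart in the treatment setting (and
#' vice versa); set `allow_unpaired = TRUE` to compare anyway, e.g. for
#' tables without pairing information.
#'
#' @param metrics data.frame with `setting`, `c_max`, `D_final_s` and
#'   optionally `seed`, `truth_id`.
#' @param reference,treatment setting labels.
#' @param allow_unpaired skip the pairing check.
#' @return data.frame per metric: means, medians, percent change and ratio
#'   for both.
#' @export
compare_settings <- function(metrics, reference, treatment,
                             allow_unpaired = FALSE) {
  if (!allow_unpaired && all(c("seed", "truth_id") %in% names(metrics))) {
    key <- function(s) {
      sub <- metrics[metrics$setting == s, ]
      sort(paste(sub$seed, sub$truth_id))
    }
    if (!identical(key(reference), key(treatment)))
      stop("settings '", reference, "' and '", treatment,
           "' are not paired ROI-for-ROI; pass allow_unpaired = TRUE to ",
           "compare anyway")
  }
  s <- summarize_cohort(metrics)
  out <- list()
  for (m in c("c_max", "D_final_s")) {
    r <- s[s$setting == reference & s$metric == m, ]
    t <- s[s$setting == treatment & s$metric == m, ]
    if (!nrow(r) || !nrow(t)) next
    pm <- percent_change(r$mean, t$mean)
    pq <- percent_change(r$median, t$median)
    out[[m]] <- data.frame(metric = m, reference = reference, treatment = treatment,
                           mean_ref = r$mean, mean_treat = t$mean,
                           mean_percent = pm$percent, mean_ratio = pm$ratio,
                           median_ref = r$median, median_treat = t$median,
                           median_percent = pq$percent, median_ratio = pq$ratio)
  }
  do.call(rbind, out)
}

#' Run a paired balloon / no-balloon synthetic campaign
#'
#' For each seed, one MVO setting (thrombus configuration) is generated and
#' both infusion protocols are executed against it, mirroring the paired
#' bench design; optionally a clean-chip control run (no MVO) is analyzed at
#' the same ROI positions. The per-thrombus results are pooled into one
#' table suitable for [summarize_cohort], [fraction_tables] and
#' [compare_settings].
#'
#' @param seeds integer vector, one MVO setting per seed.
#' @param n_thrombi thrombi per setting (default 14, the mean observed
#'   load).
#' @param layout,maps chip geometry (defaults built on demand).
#' @param physics,optics,boundary engine configuration.
#' @param noise render camera noise.
#' @param include_control also run the no-MVO control and evaluate it at the
#'   MVO run's ROIs.
#' @param placement_args extra arguments for [place_microthrombi].
#' @param analyze use the measurement pipeline (TRUE) or the field oracle
#'   (FALSE) for the per-thrombus table.
#' @return data.frame: one row per thrombus per case (settings
#'   `no_balloon/MVO`, `balloon/MVO` and optionally `no_balloon/no_MVO`).
#' @export
run_paired_campaign <- function(seeds, n_thrombi = 14,
                                layout = NULL, maps = NULL,
                                physics = physics_config(),
                                optics = optics_config(),
                                boundary = flow_boundary(),
                                noise = TRUE, include_control = FALSE,
                                placement_args = list(),
                                analyze = TRUE) {
  if (is.null(layout)) layout <- build_symmetric_tree()
  if (is.null(maps)) maps <- rasterize_layout(layout)
  rd <- calibrate_distal_resistance(layout, boundary, physics$viscosity_mPa_s)
  out <- list()
  for (seed in seeds) {
    thrombi <- do.call(place_microthrombi,
                       c(list(layout = layout, maps = maps, n = n_thrombi,
                              rng_seed = seed,
                              residual_lumen_factor = physics$residual_lumen_factor),
                         placement_args))
    for (cs in c("no_balloon", "balloon")) {
      proto <- protocol_config(case = cs, seed = seed)
      sim <- run_protocol(layout, maps, thrombi, proto, physics, optics,
                          boundary = boundary, noise = noise,
                          compute_truth = !analyze, distal_resistance = rd)
      tab <- if (analyze) {
        an <- analyze_experiment(sim$frames, sim$calibration, layout, maps,
                                 frame_rate_hz = proto$frame_rate_hz,
                                 heart_rate_bpm = proto$heart_rate_bpm)
        m <- match_detections(an$detections, sim$truth)
        m <- m[!is.na(m$detection) & !is.na(m$truth), , drop = FALSE]
        t2 <- an$table[m$detection, , drop = FALSE]
        t2$truth_id <- m$truth
        t2$true_class <- sim$truth$true_thrombus_occlusivity[m$truth]
        t2
      } else {
        t2 <- sim$truth$effective$table
        t2$truth_id <- seq_len(nrow(t2))
        t2$true_class <- sim$truth$true_thrombus_occlusivity
        t2
      }
      if (!is.null(tab) && nrow(tab)) {
        tab$seed <- seed; tab$case <- cs; tab$setting <- paste0(cs, "/MVO")
        out[[length(out) + 1]] <- tab
      }
      rm(sim); gc(verbose = FALSE)
    }
    if (include_control) {
      proto <- protocol_config(case = "no_balloon", seed = seed)
      sim0 <- run_protocol(layout, maps, list(), proto, physics, optics,
                           boundary = boundary, noise = noise,
                           compute_truth = FALSE, distal_resistance = rd)
      # evaluate the control at the MVO setting's ROI positions
      po <- .pixel_optics(layout, maps)
      conc_px <- sim0$field$conc[, .cv_index_vec(sim0$field$grid, po$segment,
                                                 po$station_um), drop = FALSE]
      cs0 <- concentration_stack(conc_px, po$channel_idx, maps$image_shape,
                                 sim0$field$times,
                                 valid = rep(TRUE, ncol(conc_px)))
      res0 <- classify_cohort(cs0, lapply(thrombi, function(t) t$footprint),
                              lapply(thrombi, function(t) t$occupied_segments),
                              maps, layout,
                              frame_rate_hz = proto$frame_rate_hz,
                              heart_rate_bpm = proto$heart_rate_bpm)
      t0 <- res0$table
      t0$truth_id <- seq_len(nrow(t0))
      t0$true_class <- rep(NA_character_, nrow(t0))
      t0$seed <- seed; t0$case <- "no_balloon"; t0$setting <- "no_balloon/no_MVO"
      out[[length(out) + 1]] <- t0
      rm(sim0); gc(verbose = FALSE)
    }
  }
  .rbind_fill(out)
}

# rbind data.frames with differing columns, filling the gaps with NA
.rbind_fill <- function(dfs) {
  dfs <- dfs[!vapply(dfs, is.null, TRUE)]
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}
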