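#' Randomly lodge microthrombi in the chip network
#'
#' Samples lodging sites the way embolizing debris distributes in the chip:
#' preferentially in small distal channels (site weight proportional to
#' `diameter^-small_vessel_weight`) and frequently at bifurcations, where a
#' thrombus straddles the parent and both daughter channels. The footprint is
#' the set of channel pixels within `nominal_size / 2` of the anchor point.
#'
#' Per-segment occlusivity ground truth is drawn in one of two modes:
#' \describe{
#'   \item{"probs"}{the thrombus occlusivity class is drawn first from
#'     `occlusivity_probs` (nonocclusive / semiocclusive / fully occlusive;
#'     defaults match the observed cohort composition 27/28/45).
#'     Semiocclusive draws are anchored at a bifurcation (they need at least
#'     two occupied segments) and block a random strict subset of the
#'     occupied segments, preferring the smaller channels; the junction
#'     probability of the other classes is lowered so the overall
#'     bifurcation fraction still equals `bifurcation_affinity`.}
#'   \item{"geometry"}{a segment is occlusive iff the thrombus is at least as
#'     wide as the channel (footprint covers the full local width).}
#' }
#'
#' Footprints of distinct thrombi are kept at least 3 px apart so detections
#' cannot merge.
#'
#' @param layout a `chip_layout`.
#' @param maps matching `segment_maps`.
#' @param n number of thrombi.
#' @param rng_seed integer seed (placement and occlusivity use independent
#'   substreams derived from it).
#' @param small_vessel_weight exponent of the `diameter^-w` lodging weight.
#' @param bifurcation_affinity probability that a thrombus sits at a
#'   bifurcation and straddles >= 2 segments.
#' @param nominal_size thrombus size in um.
#' @param occlusivity "probs" or "geometry" (see above).
#' @param occlusivity_probs length-3 numeric (nonocclusive, semiocclusive,
#'   fully occlusive), summing to 1.
#' @param residual_lumen_factor hydraulic resistance multiplier of a channel
#'   narrowed by a permeable (nonocclusive) thrombus segment.
#' @return list of `microthrombus` objects: id, anchor (um), footprint pixel
#'   indices, occupied_segments, per_segment_occlusive,
#'   segment_station_range, at_bifurcation, occlusivity class,
#'   residual_lumen_factor, nominal_size.
#' @export
place_microthrombi <- function(layout, maps, n, rng_seed = 1,
                               small_vessel_weight = 2,
                               bifurcation_affinity = 0.76,
                               nominal_size = 200,
                               occlusivity = c("probs", "geometry"),
                               occlusivity_probs = c(nonocclusive = 0.27,
                                                     semiocclusive = 0.28,
                                                     fully_occlusive = 0.45),
                               residual_lumen_factor = 100) {
  occlusivity <- match.arg(occlusivity)
  if (n < 0) stop("n must be >= 0")
  if (bifurcation_affinity < 0 || bifurcation_affinity > 1)
    stop("bifurcation_affinity must lie in [0, 1]")
  if (n == 0) return(list())
  stopifnot(abs(sum(occlusivity_probs) - 1) < 1e-9)

  seeds <- .substream_seeds(rng_seed, 2)
  tab <- segment_table(layout)
  sc <- maps$pixel_scale_um
  r_um <- nominal_size / 2

  # candidate interior sites: station range with a margin so the footprint
  # stays inside one segment
  margin <- r_um + 2 * sc
  interior <- tab[tab$length_um > 2 * margin, ]
  w_int <- interior$diameter_um^(-small_vessel_weight) * (interior$length_um - 2 * margin)
  # candidate junctions, weighted by the smaller (child) diameter
  bif <- layout$bifurcation_points
  child1 <- vapply(bif$parent_id, function(p) layout$segments[[as.character(p)]]$children[1], 0L)
  d_child <- tab$diameter_um[match(child1, tab$id)]
  w_bif <- d_child^(-small_vessel_weight)

  p_semi <- if (occlusivity == "probs") unname(occlusivity_probs[2]) else 0
  # junction probability of non-semi draws keeps the overall rate at the
  # requested affinity (semiocclusive thrombi always straddle a junction)
  q_other <- if (p_semi >= 1) 0 else
    min(max((bifurcation_affinity - p_semi) / (1 - p_semi), 0), 1)

  # A junction thrombus wedges into the mouth of a daughter channel: the
  # anchor sits a little distal of the junction so the footprint straddles
  # the parent (which claims the junction pixels) and the daughter(s). The
  # feasible offset window closes when the parent channel is wider than the
  # thrombus - a 200 um thrombus cannot straddle the 555 um inlet mouth.
  anchor_of <- function(at_bif) {
    if (at_bif) {
      j <- sample.int(nrow(bif), 1, prob = w_bif)
      par <- layout$segments[[as.character(bif$parent_id[j])]]
      ch <- layout$segments[[as.character(sample(par$children, 1))]]
      r_par <- par$diameter_um / 2
      # offset window: deep enough that the footprint reaches past the
      # parent's junction cap into daughter-labelled pixels, shallow enough
      # that it still touches the junction (within ~1 px)
      lo <- max(r_par - r_um + 2 * sc, sc)
      hi <- r_um + sc
      if (lo >= hi) return(NULL)
      s <- runif(1, lo, hi)
      p1 <- ch$centerline[1, ]; v <- ch$centerline[2, ] - p1
      p1 + v * s / ch$length_um
    } else {
      i <- sample.int(nrow(interior), 1, prob = w_int)
      s <- layout$segments[[as.character(interior$id[i])]]
      st <- runif(1, margin, s$length_um - margin)
      p1 <- s$centerline[1, ]; v <- s$centerline[2, ] - p1
      p1 + v * st / s$length_um
    }
  }

  ch_rows <- ((which(maps$channel_mask) - 1) %% nrow(maps$channel_mask)) + 1
  ch_cols <- ((which(maps$channel_mask) - 1) %/% nrow(maps$channel_mask)) + 1
  ch_idx <- which(maps$channel_mask)
  ch_x <- (ch_cols - 0.5) * sc
  ch_y <- (ch_rows - 0.5) * sc

  thrombi <- list()
  anchors <- matrix(numeric(0), 0, 2)
  taken_px <- integer(0)

  .with_seed(seeds[1], {
    classes <- if (occlusivity == "probs") {
      sample(c("nonocclusive", "semiocclusive", "fully_occlusive"), n,
             replace = TRUE, prob = occlusivity_probs)
    } else rep(NA_character_, n)
    bif_target <- vapply(seq_len(n), function(i) {
      if (identical(classes[i], "semiocclusive")) TRUE
      else runif(1) < (if (occlusivity == "probs") q_other else bifurcation_affinity)
    }, TRUE)
    # the chip offers a limited number of junctions a 200 um thrombus can
    # straddle; flip any excess non-semi junction targets to interior sites
    n_sites <- sum(vapply(bif$parent_id, function(p) {
      r_par <- layout$segments[[as.character(p)]]$diameter_um / 2
      max(r_par - r_um + 2 * sc, sc) < r_um + sc
    }, TRUE))
    excess <- sum(bif_target) - n_sites
    if (excess > 0) {
      flip <- which(bif_target & classes != "semiocclusive")
      bif_target[tail(flip, excess)] <- FALSE
    }

    # junction sites are scarce: lodge bifurcation-targeted thrombi first so
    # interior anchors cannot crowd the junctions out
    for (i in order(!bif_target)) {
      at_bif_target <- bif_target[i]
      placed <- FALSE
      for (attempt in 1:2400) {
        # junction sites can saturate; after enough failures a non-semi
        # thrombus falls back to an interior site (semiocclusive ones need
        # the junction's >= 2 segments)
        if (attempt > 1200 && at_bif_target &&
            !identical(classes[i], "semiocclusive")) at_bif_target <- FALSE
        a <- anchor_of(at_bif_target)
        if (is.null(a)) next
        inside <- (ch_x - a[1])^2 + (ch_y - a[2])^2 < r_um^2
        fp <- ch_idx[inside]
        if (length(fp) < 4) next
        # footprints of distinct thrombi must stay > 3 px apart so their
        # detections cannot merge under 8-connectivity
        if (length(taken_px) && .min_px_dist2(fp, taken_px, nrow(maps$channel_mask)) <= 9) next
        segs_fp <- maps$segment_labels[fp]
        occ <- sort(unique(segs_fp))
        if (length(occ) > 5) next
        if (at_bif_target && length(occ) < 2) next
        if (!at_bif_target && length(occ) != 1) next
        # a thrombus can only occlude channels no wider than itself: the
        # drawn class keeps being resampled to a geometrically feasible site
        d_occ <- tab$diameter_um[match(occ, tab$id)]
        if (identical(classes[i], "fully_occlusive") && !all(d_occ <= nominal_size)) next
        if (identical(classes[i], "semiocclusive")) {
          # a semiocclusive thrombus must leave an open daughter: it blocks
          # one occludable daughter channel of the junction it straddles
          kids <- occ[tab$parent[match(occ, tab$id)] %in% occ]
          if (!any(tab$diameter_um[match(kids, tab$id)] <= nominal_size)) next
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not lodge thrombus ", i,
                        " (n exceeds the available distinct sites)")
      st_range <- lapply(occ, function(sg) {
        st <- maps$station_um[fp[segs_fp == sg]]
        range(st)
      })
      thrombi[[i]] <- list(id = i, anchor_um = a, footprint = fp,
                           occupied_segments = occ,
                           segment_station_range = st_range,
                           at_bifurcation = length(occ) > 1,
                           nominal_size = nominal_size,
                           residual_lumen_factor = residual_lumen_factor,
                           occlusivity_class = classes[i])
      anchors <- rbind(anchors, a)
      taken_px <- c(taken_px, fp)
    }
  })

  # occlusivity flags on an independent substream
  .with_seed(seeds[2], {
    for (i in seq_along(thrombi)) {
      th <- thrombi[[i]]
      k <- length(th$occupied_segments)
      d_occ <- tab$diameter_um[match(th$occupied_segments, tab$id)]
      flags <- if (occlusivity == "geometry") {
        nominal_size >= d_occ
      } else switch(th$occlusivity_class,
        nonocclusive = rep(FALSE, k),
        fully_occlusive = rep(TRUE, k),
        semiocclusive = {
          # block exactly one occludable daughter channel of the straddled
          # junction: the parent and at least one daughter stay open, so the
          # concentration rule applied to the thrombus in isolation
          # reproduces the semiocclusive label (blocking every daughter
          # would darken the parent's whole distal subtree and read as
          # fully occlusive)
          kids <- th$occupied_segments[
            tab$parent[match(th$occupied_segments, tab$id)] %in%
              th$occupied_segments]
          kids <- kids[tab$diameter_um[match(kids, tab$id)] <= th$nominal_size]
          pick <- if (length(kids) > 1) sample(kids, 1) else kids
          th$occupied_segments == pick
        })
      th$per_segment_occlusive <- flags
      th$occlusivity_class <- aggregate_occlusivity(flags)
      thrombi[[i]] <- structure(th, class = "microthrombus")
    }
  })
  thrombi
}

#' Aggregate per-segment occlusivity flags into the thrombus class
#'
#' A thrombus is nonocclusive when none of its occupied segments is
#' occlusive, fully occlusive when all are, and semiocclusive otherwise.
#'
#' @param flags logical vector of per-segment occlusivity.
#' @return one of "nonocclusive", "semiocclusive", "fully_occlusive".
#' @export
aggregate_occlusivity <- function(flags) {
  if (!length(flags)) stop("at least one per-segment flag is required")
  if (all(flags)) "fully_occlusive" else if (!any(flags)) "nonocclusive" else "semiocclusive"
}

#' Identify thrombi shadowed by other thrombi's occlusions
#'
#' A thrombus is shadowed when every channel it occupies is cut off from the
#' inlet by a segment another thrombus fully occludes (on the segment itself
#' or on its feed path). No dye can reach a shadowed thrombus, so any
#' concentration-based classification reports it as fully occlusive and
#' no-contact regardless of its own occlusivity; parameter-recovery
#' estimates of the class mix therefore condition on unshadowed thrombi.
#'
#' @param layout a `chip_layout`.
#' @param thrombi list of `microthrombus`.
#' @return logical vector, TRUE where shadowed.
#' @export
shadowed_thrombi <- function(layout, thrombi) {
  tab <- segment_table(layout)
  ancestors <- function(id) {
    out <- integer(0)
    p <- tab$parent[match(id, tab$id)]
    while (!is.na(p)) { out <- c(out, p); p <- tab$parent[match(p, tab$id)] }
    out
  }
  vapply(seq_along(thrombi), function(i) {
    blockers <- unique(unlist(lapply(thrombi[-i], function(o)
      o$occupied_segments[o$per_segment_occlusive])))
    if (!length(blockers)) return(FALSE)
    all(vapply(thrombi[[i]]$occupied_segments, function(s)
      any(c(s, ancestors(s)) %in% blockers), TRUE))
  }, TRUE)
}

# squared pixel distance between the closest pixels of two linear index sets
.min_px_dist2 <- function(a, b, nrow_img) {
  ar <- (a - 1L) %% nrow_img; ac <- (a - 1L) %/% nrow_img
  br <- (b - 1L) %% nrow_img; bc <- (b - 1L) %/% nrow_img
  # bounding-box prefilter
  if (min(ar) > max(br) + 4 || min(br) > max(ar) + 4 ||
      min(ac) > max(bc) + 4 || min(bc) > max(ac) + 4) return(Inf)
  min(outer(ar, br, "-")^2 + outer(ac, bc, "-")^2)
}

# derive k reproducible sub-seeds (< 2^31) from one master seed
.substream_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
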