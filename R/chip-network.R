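#' Build the mirror-symmetric arteriolar chip network
#'
#' Constructs the vessel-tree geometry of the microfluidic chip: two
#' mirror-symmetric strict binary trees (one per inlet), each spanning four
#' Strahler-type orders (8 down to 5), embedded in a raster of the given
#' shape. The left tree grows from the left image edge; the right tree is its
#' exact mirror image about the vertical centreline.
#'
#' Orders follow coronary arteriolar morphometry: the order-8 inlet channel
#' (555 um) bifurcates down to sixteen order-5 leaves. Diameters must decrease
#' with order. Per-generation lengths and branching offsets are configurable
#' because only the diameter range is fixed by the chip design; the defaults
#' embed the tree in a 256 x 512 raster at 15 um/px.
#'
#' @param order_diameters named numeric, channel diameter in um per order
#'   ("8","7","6","5").
#' @param order_lengths named numeric, segment length in um per order.
#' @param pixel_scale um per pixel (default 15, so 16 px = 240 um).
#' @param image_shape integer (rows, cols) of the raster.
#' @param order_offsets named numeric, lateral offset in um of each child
#'   branch from its parent axis, per child order ("7","6","5"). Must be
#'   smaller than the corresponding segment length.
#' @param inlet_margin_um distance of the inlet from the image edge.
#' @return A `chip_layout` object: list of `segments` (id, order, diameter_um,
#'   length_um, parent, children, centerline), `inlet_ids`, `pixel_scale_um`,
#'   `image_shape`, `mirror_symmetric`, `bifurcation_points`.
#' @export
build_symmetric_tree <- function(order_diameters = c("8" = 555, "7" = 300, "6" = 180, "5" = 80),
                                 order_lengths = c("8" = 1500, "7" = 1200, "6" = 750, "5" = 525),
                                 pixel_scale = 15,
                                 image_shape = c(256L, 512L),
                                 order_offsets = c("7" = 900, "6" = 450, "5" = 225),
                                 inlet_margin_um = 300) {
  ords <- c("8", "7", "6", "5")
  if (!all(ords %in% names(order_diameters)) || !all(ords %in% names(order_lengths)))
    stop("order_diameters and order_lengths must name orders 8,7,6,5")
  d <- order_diameters[ords]; L <- order_lengths[ords]
  if (any(d <= 0) || any(L <= 0)) stop("diameters and lengths must be positive")
  if (any(diff(d) >= 0)) stop("diameters must decrease monotonically from order 8 to 5")
  for (o in c("7", "6", "5")) {
    if (order_offsets[[o]] >= order_lengths[[o]])
      stop("layout error: branch offset must be smaller than segment length for order ", o)
  }
  rows <- as.integer(image_shape[1]); cols <- as.integer(image_shape[2])
  w_um <- cols * pixel_scale; h_um <- rows * pixel_scale
  y0 <- h_um / 2

  # left tree: ids 1..15 in breadth-first order (1 root, 2-3 order 7, 4-7
  # order 6, 8-15 order 5)
  segs <- vector("list", 30)
  segs[[1]] <- list(id = 1L, order = 8L,
                    diameter_um = unname(d["8"]), length_um = unname(L["8"]),
                    parent = NA_integer_, children = c(2L, 3L),
                    centerline = rbind(c(inlet_margin_um, y0),
                                       c(inlet_margin_um + L[["8"]], y0)))
  gen <- list(c(2L, 3L), 4:7, 8:15)
  gen_ord <- c("7", "6", "5")
  for (g in seq_along(gen)) {
    o <- gen_ord[g]
    ids <- gen[[g]]
    for (k in seq_along(ids)) {
      id <- ids[k]
      parent <- id %/% 2L
      side <- if (id %% 2L == 0L) -1 else 1    # even child branches up (-y)
      p_end <- segs[[parent]]$centerline[2, ]
      dy <- side * order_offsets[[o]]
      dx <- sqrt(order_lengths[[o]]^2 - dy^2)
      child_end <- c(p_end[1] + dx, p_end[2] + dy)
      children <- if (o == "5") integer(0) else c(2L * id, 2L * id + 1L)
      segs[[id]] <- list(id = as.integer(id), order = as.integer(o),
                         diameter_um = unname(d[o]), length_um = unname(L[[o]]),
                         parent = as.integer(parent), children = children,
                         centerline = rbind(p_end, child_end))
    }
  }
  # right tree: exact mirror about the vertical midline, ids 16..30
  for (id in 1:15) {
    s <- segs[[id]]
    m <- s
    m$id <- as.integer(id + 15L)
    m$parent <- if (is.na(s$parent)) NA_integer_ else as.integer(s$parent + 15L)
    m$children <- if (length(s$children)) as.integer(s$children + 15L) else integer(0)
    cl <- s$centerline
    cl[, 1] <- w_um - cl[, 1]
    m$centerline <- cl
    segs[[id + 15L]] <- m
  }
  names(segs) <- as.character(1:30)

  layout <- structure(list(
    segments = segs,
    inlet_ids = c(1L, 16L),
    pixel_scale_um = pixel_scale,
    image_shape = c(rows, cols),
    mirror_symmetric = TRUE,
    bifurcation_points = .bifurcation_table(segs)
  ), class = "chip_layout")
  .validate_layout(layout)
  layout
}

#' Assemble a chip layout from an explicit segment table
#'
#' Lower-level constructor used for custom geometries (single test channels,
#' asymmetric fixtures). Each element of `segments` must carry id, order,
#' diameter_um, length_um, parent (NA for an inlet), children and a 2-column
#' centerline matrix in chip um coordinates.
#'
#' @param segments list of segment descriptions.
#' @param inlet_ids integer ids of root segments.
#' @param pixel_scale um per pixel.
#' @param image_shape integer (rows, cols).
#' @param mirror_symmetric logical flag.
#' @param validate check geometric and topological invariants (default TRUE).
#' @return a `chip_layout`.
#' @export
chip_layout <- function(segments, inlet_ids, pixel_scale = 15,
                        image_shape = c(256L, 512L), mirror_symmetric = FALSE,
                        validate = TRUE) {
  names(segments) <- as.character(vapply(segments, function(s) s$id, 0))
  layout <- structure(list(
    segments = segments,
    inlet_ids = as.integer(inlet_ids),
    pixel_scale_um = pixel_scale,
    image_shape = as.integer(image_shape),
    mirror_symmetric = isTRUE(mirror_symmetric),
    bifurcation_points = .bifurcation_table(segments)
  ), class = "chip_layout")
  if (validate) .validate_layout(layout)
  layout
}

.bifurcation_table <- function(segs) {
  rows <- lapply(segs, function(s) {
    if (!length(s$children)) return(NULL)
    data.frame(parent_id = s$id, x_um = s$centerline[nrow(s$centerline), 1],
               y_um = s$centerline[nrow(s$centerline), 2])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(parent_id = integer(0), x_um = numeric(0), y_um = numeric(0))
  rownames(out) <- NULL
  out
}

.validate_layout <- function(layout) {
  segs <- layout$segments
  ids <- vapply(segs, function(s) s$id, 0L)
  if (anyDuplicated(ids)) stop("segment ids must be unique")
  sc <- layout$pixel_scale_um
  w_um <- layout$image_shape[2] * sc; h_um <- layout$image_shape[1] * sc
  for (s in segs) {
    if (s$diameter_um <= 0 || s$length_um <= 0) stop("diameter and length must be positive")
    r <- s$diameter_um / 2
    cl <- s$centerline
    if (any(cl[, 1] < r - 1e-9) || any(cl[, 1] > w_um - r + 1e-9) ||
        any(cl[, 2] < r - 1e-9) || any(cl[, 2] > h_um - r + 1e-9))
      stop("layout error: channel extends outside the image raster")
    if (!is.na(s$parent)) {
      p <- segs[[as.character(s$parent)]]
      gap <- sqrt(sum((p$centerline[nrow(p$centerline), ] - cl[1, ])^2))
      if (gap > sc) stop("layout error: centerline does not meet its parent junction")
      if (s$order != p$order - 1L) stop("child order must be parent order - 1")
    }
    for (ch in s$children) {
      if (!as.character(ch) %in% names(segs)) stop("unknown child id ", ch)
    }
  }
  # no channel overlap between segments that do not share a junction
  n <- length(segs)
  sl <- unname(segs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- sl[[i]]; b <- sl[[j]]
    related <- identical(a$parent, b$id) || identical(b$parent, a$id) ||
      (!is.na(a$parent) && !is.na(b$parent) && a$parent == b$parent)
    if (related) next
    if (.segseg_dist(a$centerline, b$centerline) < (a$diameter_um + b$diameter_um) / 2)
      stop("layout error: channels ", a$id, " and ", b$id, " overlap")
  }
  invisible(layout)
}

# minimum distance between two 2-point centerline segments
.segseg_dist <- function(a, b) {
  dpt <- function(p, s) {
    v <- s[2, ] - s[1, ]; w <- p - s[1, ]
    t <- sum(v * w) / max(sum(v * v), 1e-300)
    t <- min(max(t, 0), 1)
    sqrt(sum((s[1, ] + t * v - p)^2))
  }
  # sample-based lower bound is unreliable; use endpoint projections plus a
  # fine sampling of both segments (segments here are short and straight)
  ts <- seq(0, 1, length.out = 33)
  pa <- cbind(a[1, 1] + ts * (a[2, 1] - a[1, 1]), a[1, 2] + ts * (a[2, 2] - a[1, 2]))
  min(c(apply(pa, 1, dpt, s = b), dpt(b[1, ], a), dpt(b[2, ], a)))
}

#' Rasterize a chip layout into channel and segment label maps
#'
#' Draws every channel as a stroke of width `diameter / pixel_scale` along its
#' centerline (round caps, so junctions are watertight). Junction pixels
#' claimed by several segments are assigned to the higher-order (larger)
#' segment; among equal orders the higher id wins, which makes label maps
#' deterministic. Alongside the labels, the per-pixel arc-length station and
#' the radial offset from the centerline are recorded; both are needed by the
#' transport-to-pixel mapping and the optical chord model.
#'
#' Mirror-symmetric layouts are rasterized by drawing the left tree and
#' mirroring its pixel sets, which makes the raster exactly symmetric.
#'
#' @param layout a `chip_layout`.
#' @return a `segment_maps` object: `channel_mask` (logical rows x cols),
#'   `segment_labels` (integer, 0 outside channels), `station_um`,
#'   `offset_um` (numeric, NA outside), `bifurcation_px` (data.frame row, col,
#'   0-based), `pixel_scale_um`.
#' @export
rasterize_layout <- function(layout) {
  rows <- layout$image_shape[1]; cols <- layout$image_shape[2]
  sc <- layout$pixel_scale_um
  labels <- matrix(0L, rows, cols)
  station <- matrix(NA_real_, rows, cols)
  offset <- matrix(NA_real_, rows, cols)

  segs <- layout$segments
  ord <- vapply(segs, function(s) s$order, 0L)
  ids <- vapply(segs, function(s) s$id, 0L)
  draw_order <- order(ord, ids)   # ascending: higher order drawn later, wins

  mirror <- isTRUE(layout$mirror_symmetric)
  half <- if (mirror) ids <= 15L else rep(TRUE, length(ids))

  put <- function(id, px_row, px_col, st, off) {
    idx <- cbind(px_row, px_col)
    labels[idx] <<- id
    station[idx] <<- st
    offset[idx] <<- off
  }

  for (k in draw_order) {
    s <- segs[[k]]
    if (mirror && s$id > 15L) next
    hit <- .stroke_pixels(s$centerline, s$diameter_um, sc, rows, cols)
    if (nrow(hit) == 0) next
    put(s$id, hit[, "row"], hit[, "col"], hit[, "station"], hit[, "offset"])
    if (mirror) {
      # mirrored twin: same rows, mirrored columns, identical stations/offsets
      put(s$id + 15L, hit[, "row"], cols + 1L - hit[, "col"], hit[, "station"], hit[, "offset"])
    }
  }
  # drawing in one ascending pass means a later (higher-order) segment
  # overwrote junction pixels; redo the pass so station/offset stay consistent
  # with the final label: they were written together, so they already are.

  bif <- layout$bifurcation_points
  bif_px <- data.frame(row = pmin(pmax(floor(bif$y_um / sc), 0), rows - 1),
                       col = pmin(pmax(floor(bif$x_um / sc), 0), cols - 1),
                       parent_id = bif$parent_id)
  structure(list(channel_mask = labels > 0L,
                 segment_labels = labels,
                 station_um = station,
                 offset_um = offset,
                 bifurcation_px = bif_px,
                 pixel_scale_um = sc,
                 image_shape = c(rows, cols)),
            class = "segment_maps")
}

# pixels whose centre lies strictly within diameter/2 of the (finite)
# centerline; returns 1-based row/col plus station (um along centerline,
# clamped to [0, L]) and radial offset (um). Pixel centres sit at
# ((col-1)+0.5, (row-1)+0.5) * pixel_scale in chip um coordinates.
.stroke_pixels <- function(cl, diameter_um, sc, rows, cols) {
  r <- diameter_um / 2
  p1 <- cl[1, ]; p2 <- cl[nrow(cl), ]
  xmin <- max(floor((min(p1[1], p2[1]) - r) / sc), 0)
  xmax <- min(ceiling((max(p1[1], p2[1]) + r) / sc), cols - 1)
  ymin <- max(floor((min(p1[2], p2[2]) - r) / sc), 0)
  ymax <- min(ceiling((max(p1[2], p2[2]) + r) / sc), rows - 1)
  if (xmax < xmin || ymax < ymin)
    return(matrix(numeric(0), 0, 4, dimnames = list(NULL, c("row", "col", "station", "offset"))))
  cgrid <- xmin:xmax; rgrid <- ymin:ymax
  px <- (rep(cgrid, each = length(rgrid)) + 0.5) * sc
  py <- (rep(rgrid, times = length(cgrid)) + 0.5) * sc
  v <- p2 - p1
  len2 <- sum(v * v)
  t <- ((px - p1[1]) * v[1] + (py - p1[2]) * v[2]) / len2
  tc <- pmin(pmax(t, 0), 1)
  dx <- p1[1] + tc * v[1] - px
  dy <- p1[2] + tc * v[2] - py
  dist <- sqrt(dx * dx + dy * dy)
  keep <- dist < r
  cbind(row = rep(rgrid, times = length(cgrid))[keep] + 1L,
        col = rep(cgrid, each = length(rgrid))[keep] + 1L,
        station = tc[keep] * sqrt(len2),
        offset = dist[keep])
}

#' Strict descendants of a segment
#'
#' @param layout a `chip_layout`.
#' @param segment_id integer segment id.
#' @return integer vector of all strict descendants (excluding the segment
#'   itself); empty for a leaf.
#' @export
distal_subtree <- function(layout, segment_id) {
  key <- as.character(segment_id)
  if (!key %in% names(layout$segments)) stop("unknown segment id ", segment_id)
  out <- integer(0)
  queue <- layout$segments[[key]]$children
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    out <- c(out, id)
    queue <- c(queue, layout$segments[[as.character(id)]]$children)
  }
  out
}

#' Segment attribute table
#'
#' @param layout a `chip_layout`.
#' @return data.frame with id, order, diameter_um, length_um, parent, n_children.
#' @export
segment_table <- function(layout) {
  segs <- layout$segments
  data.frame(id = vapply(segs, function(s) s$id, 0L),
             order = vapply(segs, function(s) s$order, 0L),
             diameter_um = vapply(segs, function(s) s$diameter_um, 0),
             length_um = vapply(segs, function(s) s$length_um, 0),
             parent = vapply(segs, function(s) if (is.na(s$parent)) NA_integer_ else s$parent, NA_integer_),
             n_children = vapply(segs, function(s) length(s$children), 0L),
             row.names = NULL)
}

#' Write / read a chip layout as versioned JSON
#'
#' The on-disk format is `mvochip-layout/1`: segment records with centerlines
#' in chip um coordinates plus the raster metadata.
#'
#' @param layout a `chip_layout`.
#' @param path file path.
#' @return `read_chip_layout` returns a `chip_layout`.
#' @export
write_chip_layout <- function(layout, path) {
  segs <- lapply(unname(layout$segments), function(s) {
    list(id = s$id, order = s$order, diameter_um = s$diameter_um,
         length_um = s$length_um,
         parent = s$parent,     # NA serializes as null for inlet roots
         children = as.list(s$children),
         centerline = apply(s$centerline, 1, function(p) c(p[1], p[2]), simplify = FALSE))
  })
  obj <- list(format = "mvochip-layout/1",
              segments = segs,
              inlets = as.list(layout$inlet_ids),
              pixel_scale_um = layout$pixel_scale_um,
              image_shape = as.list(layout$image_shape),
              mirror_symmetric = layout$mirror_symmetric)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_chip_layout
#' @export
read_chip_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mvochip-layout/1"))
    stop("not an mvochip-layout/1 file")
  segs <- lapply(obj$segments, function(s) {
    cl <- do.call(rbind, lapply(s$centerline, function(p) c(p[[1]], p[[2]])))
    list(id = as.integer(s$id), order = as.integer(s$order),
         diameter_um = as.numeric(s$diameter_um), length_um = as.numeric(s$length_um),
         parent = if (is.null(s$parent)) NA_integer_ else as.integer(s$parent),
         children = as.integer(unlist(s$children)),
         centerline = cl)
  })
  chip_layout(segs, inlet_ids = as.integer(unlist(obj$inlets)),
              pixel_scale = as.numeric(obj$pixel_scale_um),
              image_shape = as.integer(unlist(obj$image_shape)),
              mirror_symmetric = isTRUE(obj$mirror_symmetric))
}

#' @export
print.chip_layout <- function(x, ...) {
  tab <- segment_table(x)
  cat("chip_layout:", nrow(tab), "segments,", sum(tab$n_children == 0), "leaves,",
      length(x$inlet_ids), "inlets\n")
  cat("  diameters", min(tab$diameter_um), "-", max(tab$diameter_um), "um,",
      "raster", x$image_shape[1], "x", x$image_shape[2], "at",
      x$pixel_scale_um, "um/px\n")
  invisible(x)
}
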