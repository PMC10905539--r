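test_that("default tree has two mirror 4-level binary trees with valid orders", {
  lay <- default_layout()
  tab <- segment_table(lay)
  expect_equal(nrow(tab), 30)
  expect_equal(sum(tab$order == 5 & tab$n_children == 0), 16)
  expect_equal(sort(unique(tab$order)), 5:8)
  expect_true(all(tab$diameter_um >= 50 & tab$diameter_um <= 555))
  expect_true(all(tab$diameter_um > 0 & tab$length_um > 0))
  # child order = parent order - 1; centerline meets parent junction
  for (s in lay$segments) {
    if (is.na(s$parent)) next
    p <- lay$segments[[as.character(s$parent)]]
    expect_equal(s$order, p$order - 1L)
    gap <- sqrt(sum((p$centerline[2, ] - s$centerline[1, ])^2))
    expect_lte(gap, lay$pixel_scale_um)
  }
  # diameters at the chip's stated extremes remain inside [50, 555]
  lay2 <- build_symmetric_tree(order_diameters = c("8" = 555, "7" = 280, "6" = 150, "5" = 50))
  expect_true(all(segment_table(lay2)$diameter_um >= 50 &
                    segment_table(lay2)$diameter_um <= 555))
})

test_that("rasterization is mirror symmetric, conservative and deterministic", {
  lay <- default_layout()
  maps <- rasterize_layout(lay)
  m <- maps$channel_mask
  half <- ncol(m) / 2
  expect_identical(m[, 1:half], m[, ncol(m):(half + 1)])
  # segment labels cover the mask exactly and every segment appears
  expect_equal(sum(maps$segment_labels > 0), sum(m))
  expect_setequal(unique(maps$segment_labels[maps$segment_labels > 0]),
                  segment_table(lay)$id)
  expect_equal(sum(tabulate(maps$segment_labels[maps$segment_labels > 0], 30)),
               sum(m))
  # bit-for-bit determinism
  maps2 <- rasterize_layout(build_symmetric_tree())
  expect_identical(maps$segment_labels, maps2$segment_labels)
})

test_that("stroke width and pixel area follow the channel geometry", {
  # 150 um channel at 15 um/px on a pixel boundary: stroke exactly 10 px
  seg <- list(id = 1L, order = 8L, diameter_um = 150, length_um = 1500,
              parent = NA_integer_, children = integer(0),
              centerline = rbind(c(300, 960), c(1800, 960)))
  lay <- chip_layout(list(seg), 1L, pixel_scale = 15, image_shape = c(128L, 256L))
  maps <- rasterize_layout(lay)
  widths <- colSums(maps$channel_mask)
  expect_equal(max(widths), 10)
  # pixel area ~ length * diameter / scale^2 (round caps add a few percent)
  analytic <- 1500 * 150 / 15^2
  expect_lt(abs(sum(maps$channel_mask) - analytic) / analytic, 0.15)
  # empty layout -> all-false mask
  empty <- chip_layout(list(), integer(0), pixel_scale = 15, image_shape = c(16L, 16L))
  expect_false(any(rasterize_layout(empty)$channel_mask))
})

test_that("distal_subtree matches a brute-force traversal and partitions the chip", {
  lay <- default_layout()
  tab <- segment_table(lay)
  # independent oracle: repeated parent-pointer sweep
  oracle <- function(id) {
    desc <- integer(0); frontier <- id
    repeat {
      nxt <- tab$id[!is.na(tab$parent) & tab$parent %in% frontier]
      nxt <- setdiff(nxt, desc)
      if (!length(nxt)) break
      desc <- c(desc, nxt); frontier <- nxt
    }
    sort(desc)
  }
  for (id in tab$id) expect_equal(sort(distal_subtree(lay, id)), oracle(id))
  leaves <- tab$id[tab$n_children == 0]
  for (id in leaves) expect_length(distal_subtree(lay, id), 0)
  expect_length(distal_subtree(lay, 1L), 14)
  expect_setequal(c(1L, 16L, distal_subtree(lay, 1L), distal_subtree(lay, 16L)),
                  tab$id)
  # topology property: every non-root is in its parent's distal subtree
  for (s in lay$segments) {
    if (is.na(s$parent)) next
    expect_true(s$id %in% distal_subtree(lay, s$parent))
  }
  expect_error(distal_subtree(lay, 999L), "unknown")
})

test_that("layout JSON round-trips", {
  lay <- default_layout()
  path <- tempfile(fileext = ".json")
  write_chip_layout(lay, path)
  lay2 <- read_chip_layout(path)
  expect_equal(segment_table(lay2), segment_table(lay))
  expect_equal(lay2$inlet_ids, lay$inlet_ids)
  expect_equal(lay2$pixel_scale_um, lay$pixel_scale_um)
  expect_identical(rasterize_layout(lay2)$segment_labels,
                   rasterize_layout(lay)$segment_labels)
})

test_that("impossible embeddings raise layout errors", {
  expect_error(build_symmetric_tree(image_shape = c(40L, 60L)), "layout error")
  expect_error(build_symmetric_tree(order_lengths = c("8" = 1500, "7" = 800, "6" = 750, "5" = 525)),
               "offset")
  expect_error(build_symmetric_tree(order_diameters = c("8" = 100, "7" = 300, "6" = 180, "5" = 80)),
               "monoton")
})
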