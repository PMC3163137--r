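test_that("excess red is 2R - B - G, signed, unclamped", {
  px <- array(0L, c(1, 3, 3))
  px[1, 1, ] <- c(255, 0, 0)
  px[1, 2, ] <- c(77, 77, 77)
  px[1, 3, ] <- c(100, 50, 30)
  er <- excess_red(slide_image(px, 1))
  expect_identical(as.integer(er), c(510L, 0L, 120L))

  blue <- array(0L, c(1, 1, 3)); blue[1, 1, ] <- c(0, 0, 255)
  expect_identical(as.integer(excess_red(slide_image(blue, 1))), -255L)
})

test_that("a pure-red disc on grey is recovered within one boundary pixel", {
  base <- flat_slide(100, 100, c(128, 128, 128))
  sc <- paint_disc(base, c(49.5, 49.5), 20, c(255, 0, 0))
  wall <- detect_walls(sc$image, min_wall_area_px = 0)
  mismatch <- wall$values != sc$disc
  expect_true(all(!mismatch))

  # a grey image (no red excess anywhere) has a one-level histogram
  expect_error(detect_walls(base), "degenerate")
})

test_that("wall detection finds every ring of a synthetic slide", {
  out <- small_synth(seed = 0)
  wall <- detect_walls(out$image)
  truth <- out$truth$vessel_labels
  for (i in seq_len(max(truth))) {
    # the stained annulus is the vessel disc minus its lumen; require 80%
    # of it recovered
    obj <- truth == i
    lum <- (out$image$pixels[, , 1] + out$image$pixels[, , 2] +
              out$image$pixels[, , 3]) / 3
    annulus <- obj & lum < 200
    expect_gte(sum(wall$values & annulus) / sum(annulus), 0.8)
  }
})

test_that("tissue detection recovers the blob and rejects all-glass", {
  out <- small_synth(seed = 1)
  tis <- detect_tissue(out$image, factor = 8)
  expect_equal(tis$pixel_size_um, out$image$pixel_size_um * 8)
  # ground truth at the decimated scale: majority vote per 8x8 block
  truth8 <- decimate_channel(out$truth$tissue_mask$values * 255, 8) >= 128
  overlap <- sum(tis$values & truth8) / sum(truth8)
  expect_gte(overlap, 0.95)

  # full-resolution result is consistent with the decimated one
  tis1 <- detect_tissue(out$image, factor = 1)
  expect_lt(abs(mask_area_mm2(tis1) - mask_area_mm2(tis)) /
              mask_area_mm2(tis1), 0.1)

  glass <- flat_slide(64, 64, c(245, 245, 248))
  expect_error(detect_tissue(glass), "degenerate")
})

test_that("lumens require brightness inside tissue and wall adjacency", {
  # tissue square with one red ring (bright interior) and one bare bright
  # hole far from any wall
  img <- flat_slide(120, 120, c(245, 245, 248), pixel_size_um = 1)
  tissue_vals <- matrix(FALSE, 120, 120); tissue_vals[11:110, 11:110] <- TRUE
  px <- img$pixels
  for (ch in 1:3) { p <- px[, , ch]; p[tissue_vals] <- c(205, 175, 185)[ch]; px[, , ch] <- p }
  img <- slide_image(px, 1)
  ring <- paint_disc(img, c(40, 40), 12, c(200, 40, 60))
  inner <- paint_disc(ring$image, c(40, 40), 8, c(242, 242, 242))
  hole <- paint_disc(inner$image, c(85, 85), 8, c(242, 242, 242))
  img <- hole$image
  tissue <- binary_mask(tissue_vals, 1, "tissue")
  wall <- binary_mask(ring$disc & !inner$disc, 1, "wall")

  lum <- detect_lumens(img, wall, tissue)
  expect_true(all(lum$values[inner$disc]))      # interior kept
  expect_false(any(lum$values[hole$disc]))      # far hole discarded
  expect_false(any(lum$values & wall$values))   # disjoint from wall

  # no background to estimate from
  all_tissue <- binary_mask(matrix(TRUE, 120, 120), 1, "tissue")
  expect_error(detect_lumens(img, wall, all_tissue), "bg_mean")
  expect_silent(detect_lumens(img, wall, all_tissue, bg_mean = 246))
})

test_that("every kept lumen component touches a wall after 1-px dilation", {
  out <- small_synth(seed = 2, n_vessels = 20)
  wall <- detect_walls(out$image)
  tissue <- detect_tissue(out$image)
  lum <- detect_lumens(out$image, wall, tissue)
  labs <- EBImage::bwlabel(lum$values)
  wall_dil <- EBImage::dilate(wall$values + 0, EBImage::makeBrush(3, "box")) > 0
  for (i in seq_len(max(labs)))
    expect_true(any(wall_dil[labs == i]))
})

test_that("vessel assembly is 8-connected, hole-filled, exclusion-aware", {
  # two rings joined by a single diagonal pixel bridge
  w <- matrix(FALSE, 60, 120)
  mk <- function(cr, cc, r1, r2) {
    rr <- matrix(seq_len(60) - 1, 60, 120)
    cc2 <- matrix(seq_len(120) - 1, 60, 120, byrow = TRUE)
    d2 <- (rr - cr)^2 + (cc2 - cc)^2
    d2 <= r2^2 & d2 > r1^2
  }
  w <- mk(29, 30, 8, 12) | mk(29, 56, 8, 12)
  # bridge pixel diagonally adjacent to both rings ((29,42) and (29,44)
  # 0-based are ring pixels), touching neither 4-connectedly
  w[29, 44] <- TRUE
  wall <- binary_mask(w, 1, "wall")
  lum <- binary_mask(matrix(FALSE, 60, 120), 1, "lumen")
  obj <- assemble_vessels(wall, lum)
  expect_equal(obj$n_objects, 1)
  expect_true(all(obj$vessel_mask$values[mk(29, 30, 0, 8)]))  # hole filled

  # exclusion drops whole objects and records their labels
  out <- small_synth(seed = 3, n_vessels = 10, n_confounders = 3,
                     tumor_radius_um = c(90, 110))
  seg_all <- segment_slide(out$image)
  seg_ex <- segment_slide(out$image, exclusion_mask = out$truth$confounder_mask)
  expect_equal(max(seg_ex$labels), 10)
  expect_equal(length(seg_ex$excluded_labels),
               max(seg_all$labels) - max(seg_ex$labels))
  ev <- evaluate_detection(out$truth$vessel_labels, seg_ex)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)

  expect_error(
    assemble_vessels(wall, binary_mask(matrix(FALSE, 10, 10), 1)),
    "registration")
})

test_that("segmentation is deterministic and monotone in the size filter", {
  out <- small_synth(seed = 4)
  s1 <- segment_slide(out$image)
  s2 <- segment_slide(out$image)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$wall_mask$values, s2$wall_mask$values)

  counts <- vapply(c(0, 20, 500, 5000), function(a) {
    cfg <- quant_config(min_wall_area_px = a)
    max(segment_slide(out$image, config = cfg)$labels)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("tidy and glance summarize a segmentation", {
  out <- small_synth(seed = 5)
  seg <- segment_slide(out$image)
  td <- tidy(seg)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), max(seg$labels))
  expect_true(all(td$area_um2 == td$area_px * seg$pixel_size_um^2))
  gl <- glance(seg)
  expect_equal(gl$n_vessels, max(seg$labels))
  expect_equal(gl$wall_threshold, seg$wall_threshold)
})

test_that("config round-trips through YAML and rejects unknown fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(lumen_bg_fraction = 0.85, min_wall_area_px = 10), path)
  cfg <- read_config(path)
  expect_equal(cfg$lumen_bg_fraction, 0.85)
  expect_equal(cfg$min_wall_area_px, 10L)
  expect_equal(cfg$tissue_decimation_factor, 8L)

  yaml::write_yaml(list(lumen_fraction = 0.8), path)
  expect_error(read_config(path), "lumen_fraction")
})
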